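# Classed error helpers so callers can distinguish bad arguments from
# data-driven fitting failures (unfittable voxels are routinely caught
# and dropped; invalid arguments never are).

abort <- function(message, class, call. = FALSE, ...) {
  cnd <- structure(
    class = c(class, "rsilung_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cnd)
}

abort_invalid <- function(message, ...) {
  abort(message, class = "rsilung_invalid_argument", ...)
}

abort_unfittable <- function(message, ...) {
  abort(message, class = "rsilung_unfittable_voxel", ...)
}
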