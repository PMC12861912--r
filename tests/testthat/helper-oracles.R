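# Published two-group summaries used throughout the tests: a 97-patient
# SCC (n = 30) vs AC (n = 67) cohort.
tab2 <- list(
  n_scc = 30, n_ac = 67,
  age = list(scc = c(62.47, 8.85), ac = c(61.51, 8.01)),
  f1 = list(scc = c(67.11, 17.27), ac = c(86.27, 13.01)),
  # counts: (positive, negative) per group
  smoking = list(scc = c(21, 9), ac = c(21, 46)),
  # male/female counts per group as implied by the published sex ROC
  # operating point (sensitivity 83.33%, specificity 59.70%); the
  # published descriptive table prints the AC counts the other way round
  sex_male = list(scc = c(25, 5), ac = c(27, 40))
)

# Independent constrained least-squares oracle for the compartment fit:
# box-constrained quasi-Newton minimization of the residual sum of
# squares, started away from the solution; shares no code with the NNLS
# route.
oracle_nnls <- function(basis, y) {
  rss <- function(cc) sum((y - basis %*% cc)^2)
  grad <- function(cc) -2 * drop(t(basis) %*% (y - basis %*% cc))
  fit <- optim(rep(mean(y), 3), rss, grad, method = "L-BFGS-B",
               lower = 0, control = list(factr = 1e1, maxit = 500))
  fit$par
}

# Brute-force Mann-Whitney pair count with half credit for ties.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Brute-force DeLong placement values by pair enumeration.
oracle_placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

# Random point on the 3-simplex.
rsimplex <- function() {
  e <- rexp(3)
  e / sum(e)
}

# Cohort 2x2 counts laid out as (a, b, c, d) rows = groups.
smoking_counts <- function() c(tab2$smoking$scc, tab2$smoking$ac)

# Expanded per-patient binary data matching the smoking table: scores and
# subtype labels for 97 patients.
smoking_cohort_vectors <- function() {
  list(scores = rep(c(1, 0, 1, 0), c(21, 9, 21, 46)),
       labels = rep(c("SCC", "SCC", "AC", "AC"), c(21, 9, 21, 46)))
}
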