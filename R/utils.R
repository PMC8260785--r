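# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# direction coding: +1 = rightward ("R"), -1 = leftward ("L")
.dirToChar <- function(d) ifelse(d > 0, "R", "L")
.charToDir <- function(ch) ifelse(ch == "R", 1, -1)

# round half away from zero (base round() rounds half to even)
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# one-sided p-value (rho > 0) for a Spearman correlation using the
# large-sample t approximation; ties handled by average ranks via rank()
.spearmanGreater <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- if (rho > 0) 0 else 1
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

# one-way ANOVA p-value from a trials x bins matrix: bins are the groups,
# trials the replicates (stats::oneway.test, classical equal-variance F)
.anovaBinsP <- function(trials) {
  vals <- as.vector(trials)
  grp <- factor(rep(seq_len(ncol(trials)), each = nrow(trials)))
  if (stats::sd(vals) == 0) return(NA_real_)
  out <- tryCatch(
    stats::oneway.test(vals ~ grp, var.equal = TRUE),
    error = function(e) NULL)
  if (is.null(out) || !is.finite(out$p.value)) NA_real_ else out$p.value
}

# circular (wrap-around) angular difference a - b in (-180, 180]
.angDiff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

# circularly shift a matrix by integer (rows, cols)
.circShift <- function(m, s) {
  s <- as.integer(round(s))
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - s[1]) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - s[2]) %% nc) + 1
  m[ri, ci, drop = FALSE]
}
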