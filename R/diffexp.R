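# fast internal path: z statistics only, given column index sets
.tstats <- function(X, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  X1 <- X[, i1, drop = FALSE]
  X2 <- X[, i2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss1 <- rowSums(X1 * X1) - n1 * m1^2
  ss2 <- rowSums(X2 * X2) - n2 * m2^2
  vp <- pmax(ss1 + ss2, 0) / (n1 + n2 - 2)
  se <- sqrt(vp * (1 / n1 + 1 / n2))
  z <- (m1 - m2) / se
  degenerate <- se == 0
  z[degenerate] <- 0
  list(z = z, degenerate = degenerate)
}

resolve_groups <- function(expr, groups, levels = NULL) {
  if (length(groups) != ncol(expr)) {
    abort("`groups` must have one label per matrix column")
  }
  groups <- as.character(groups)
  u <- unique(groups)
  if (length(u) != 2) abort("`groups` must contain exactly two labels")
  if (is.null(levels)) {
    levels <- if (setequal(u, c("RY", "RN"))) c("RY", "RN") else sort(u)
  }
  if (!setequal(levels, u)) abort("`levels` must match the labels in `groups`")
  i1 <- which(groups == levels[1])
  i2 <- which(groups == levels[2])
  if (length(i1) < 2 || length(i2) < 2) {
    abort("each phenotype group needs at least 2 patients")
  }
  list(i1 = i1, i2 = i2, levels = levels)
}

#' Per-gene two-sample t statistics
#'
#' Pooled-variance two-sample t statistic per gene comparing the two
#' phenotype groups: `z = (mean1 - mean2) / (s_p * sqrt(1/n1 + 1/n2))`.
#' Two-sided P values come from the standard Gaussian reference by default
#' (the asymptotic analysis of the latent-group bias is phrased against the
#' standard normal); a Student-t reference with `n1 + n2 - 2` df is
#' available.
#'
#' @param expr genes-by-patients numeric matrix with gene rownames.
#' @param groups character vector of per-patient phenotype labels aligned
#'   to the columns of `expr` (two distinct values; `RY`/`RN` ordering is
#'   recognised, otherwise the first level after sorting is the "case").
#' @param levels optional length-2 character vector fixing which label is
#'   the case group (difference is `mean(levels[1]) - mean(levels[2])`).
#' @param reference `"gaussian"` (default) or `"t"` for the P-value null
#'   reference.
#' @return tibble `(gene_id, z, p, degenerate)`; genes with zero pooled
#'   variance get `z = 0`, `p = 1` and `degenerate = TRUE`.
#' @export
#' @examples
#' X <- rbind(gA = c(1, 3, 0, 2))
#' two_sample_t(X, c("RY", "RY", "RN", "RN"))
two_sample_t <- function(expr, groups, levels = NULL,
                         reference = c("gaussian", "t")) {
  reference <- arg_match(reference)
  g <- resolve_groups(expr, groups, levels)
  ts <- .tstats(expr, g$i1, g$i2)
  p <- if (reference == "gaussian") {
    2 * pnorm(-abs(ts$z))
  } else {
    2 * pt(-abs(ts$z), df = length(g$i1) + length(g$i2) - 2)
  }
  if (any(ts$degenerate)) {
    warn(sprintf("%d gene(s) with zero pooled variance; statistic set to 0",
                 sum(ts$degenerate)))
  }
  tibble(
    gene_id = rownames(expr) %||% sprintf("g%05d", seq_len(nrow(expr))),
    z = unname(ts$z),
    p = unname(p),
    degenerate = unname(ts$degenerate)
  )
}
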