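#' Compare two half-life tables
#'
#' Inner-joins two half-life tables on gene id (keeping converged genes with a
#' finite positive half-life) and reports the Spearman rank correlation and
#' the Pearson correlation. Half-life distributions are heavy-tailed, so the
#' Pearson correlation is computed on log10 half-lives by default.
#'
#' @param a,b data frames with a `gene_id` column and a `half_life` (or
#'   `half_life_hours`) column, e.g. from [fit_table()] or
#'   [read_half_lives_tsv()].
#' @param log_pearson compute the Pearson correlation on log10 half-lives
#'   (default) rather than on the linear scale.
#' @return List with `n_shared`, `r_s` (Spearman), `r_p` (Pearson), and the
#'   paired vectors `half_life_a`, `half_life_b` (named by gene id).
#' @export
compare_half_life_tables <- function(a, b, log_pearson = TRUE) {
  ha <- extract_half_lives(a)
  hb <- extract_half_lives(b)
  shared <- intersect(names(ha), names(hb))
  if (length(shared) < 4) {
    stop("need >= 4 shared genes with half-lives; got ", length(shared))
  }
  x <- ha[shared]
  y <- hb[shared]
  r_s <- stats::cor(x, y, method = "spearman")
  r_p <- if (log_pearson) stats::cor(log10(x), log10(y)) else stats::cor(x, y)
  list(n_shared = length(shared), r_s = r_s, r_p = r_p,
       half_life_a = x, half_life_b = y)
}

extract_half_lives <- function(tab) {
  if (!is.data.frame(tab) || !"gene_id" %in% names(tab)) {
    stop("half-life table must be a data frame with a gene_id column")
  }
  col <- intersect(c("half_life", "half_life_hours"), names(tab))[1]
  if (is.na(col)) stop("half-life table must carry half_life or half_life_hours")
  hl <- tab[[col]]
  keep <- is.finite(hl) & hl > 0
  if ("converged" %in% names(tab)) keep <- keep & tab$converged
  stats::setNames(hl[keep], tab$gene_id[keep])
}

#' Fisher r-to-z test for comparing two correlations
#'
#' Tests whether two independent correlation coefficients differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided
#' normal p-value. Applying the test to Spearman coefficients (as is common
#' when comparing rank correlations of half-life tables) treats them as
#' Pearson correlations; the p-value is then approximate.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes behind each coefficient, both >= 4.
#' @return List with `r1`, `r2`, `n1`, `n2`, `z`, and two-sided `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  if (any(c(n1, n2) < 4)) stop("sample sizes must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z, p = p)
}
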