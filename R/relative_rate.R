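# Tajima's one-degree-of-freedom relative rate test on 3-taxon alignments.

#' Site-pattern counts for a 3-taxon comparison
#'
#' Classifies every alignment column of the (ingroup1, ingroup2, outgroup)
#' projection: columns with a gap or N in any of the three taxa are skipped
#' entirely (complete deletion); remaining columns are `identical` (all
#' equal), `uniq1` / `uniq2` / `uniq_out` (exactly one taxon differs from
#' the identical other two), or `divergent` (all three states distinct).
#'
#' @param aln an [alignment_matrix()].
#' @param ingroup1,ingroup2,outgroup taxon names (an error if absent).
#' @return list of class `site_pattern_counts` with fields `identical`,
#'   `divergent`, `uniq1`, `uniq2`, `uniq_out`, `skipped`; their sum equals
#'   the number of alignment columns.
#' @export
site_pattern_counts <- function(aln, ingroup1, ingroup2, outgroup) {
  roles <- c(ingroup1, ingroup2, outgroup)
  missing <- setdiff(roles, aln$taxa)
  if (length(missing)) stop("role taxa not in alignment: ",
                            paste(missing, collapse = ", "))
  x <- aln$mat[ingroup1, ]; y <- aln$mat[ingroup2, ]; z <- aln$mat[outgroup, ]
  ok <- is_base(x) & is_base(y) & is_base(z)
  xy <- x == y; xz <- x == z; yz <- y == z
  out <- list(
    identical = sum(ok & xy & xz),
    divergent = sum(ok & !xy & !xz & !yz),
    uniq1     = sum(ok & yz & !xy),
    uniq2     = sum(ok & xz & !xy),
    uniq_out  = sum(ok & xy & !xz),
    skipped   = sum(!ok),
    ingroup1 = ingroup1, ingroup2 = ingroup2, outgroup = outgroup)
  class(out) <- "site_pattern_counts"
  out
}

#' Tajima relative rate test statistic
#'
#' Under rate equality the lineage-specific site counts `m1` and `m2` have
#' equal expectation, and `(m1 - m2)^2 / (m1 + m2)` is approximately
#' chi-square distributed with 1 degree of freedom. The p-value is the
#' upper-tail probability (computed, not table-looked-up).
#'
#' @param m1,m2 ingroup1- and ingroup2-specific site counts
#'   (`m1 + m2 > 0`; the test is undefined otherwise).
#' @return list of class `rate_test` with `m1`, `m2`, `chi_square`,
#'   `df = 1`, `p_value` (`p = 1` iff `m1 == m2`).
#' @export
tajima_test <- function(m1, m2) {
  if (m1 + m2 <= 0) stop("test undefined: m1 + m2 must be positive")
  chi <- (m1 - m2)^2 / (m1 + m2)
  out <- list(m1 = m1, m2 = m2, chi_square = chi, df = 1L,
              p_value = pchisq(chi, df = 1L, lower.tail = FALSE))
  class(out) <- "rate_test"
  out
}

#' Format a p-value in the conventional table style
#'
#' Three significant figures, with values below 0.001 reported as
#' `"< 0.001"`.
#'
#' @param p a p-value in `(0, 1]`.
#' @return a character scalar.
#' @export
format_pvalue <- function(p) {
  if (p < 0.001) "< 0.001" else format(signif(p, 3L))
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf("<rate_test> m1 = %d, m2 = %d: chi-square = %.2f (df 1), p %s\n",
              x$m1, x$m2, x$chi_square,
              sub("^(?=[0-9])", "= ", format_pvalue(x$p_value), perl = TRUE)))
  invisible(x)
}

#' Run Tajima relative rate tests over taxon pairs
#'
#' Projects the alignment onto each (ingroup1, ingroup2, outgroup) triplet,
#' counts site patterns and applies [tajima_test()]. The `slower` label
#' names the lineage with the smaller lineage-specific count when the test
#' is significant at `alpha`.
#'
#' @param aln an [alignment_matrix()].
#' @param pairs list of length-2 character vectors `(ingroup1, ingroup2)`.
#' @param outgroup outgroup taxon name.
#' @param alpha significance level for the `slower` call (default 0.05).
#' @return data frame with one row per pair: `ingroup1`, `ingroup2`,
#'   `outgroup`, `identical`, `divergent`, `uniq1`, `uniq2`, `uniq_out`,
#'   `chi_square`, `p_value`, `p_formatted`, `slower`.
#' @export
run_rate_tests <- function(aln, pairs, outgroup, alpha = 0.05) {
  rows <- lapply(pairs, function(p) {
    cnt <- site_pattern_counts(aln, p[1L], p[2L], outgroup)
    tst <- if (cnt$uniq1 + cnt$uniq2 == 0L) {
      # no lineage-specific sites at all: the equal-rate limit
      list(chi_square = 0, p_value = 1)
    } else {
      tajima_test(cnt$uniq1, cnt$uniq2)
    }
    slower <- if (tst$p_value < alpha) {
      if (cnt$uniq1 < cnt$uniq2) p[1L] else p[2L]
    } else NA_character_
    data.frame(ingroup1 = p[1L], ingroup2 = p[2L], outgroup = outgroup,
               identical = cnt$identical, divergent = cnt$divergent,
               uniq1 = cnt$uniq1, uniq2 = cnt$uniq2, uniq_out = cnt$uniq_out,
               chi_square = tst$chi_square, p_value = tst$p_value,
               p_formatted = format_pvalue(tst$p_value), slower = slower)
  })
  do.call(rbind, rows)
}
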