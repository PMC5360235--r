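# Expression-binned ("local") Z-score transformation. Genes are grouped by
# expression level into bins of 300, and each gene's value is standardized
# against the mean and sample standard deviation of the OTHER genes in its
# bin (leave-one-out), so the statistic absorbs the depth-dependent
# variance of low-count genes.

#' Expression-binned local Z-scores
#'
#' Genes are sorted by expression in descending order and cut into
#' consecutive bins of \code{bin_size}. A final remainder shorter than
#' \code{bin_size/2} is absorbed into the previous bin; otherwise it stands
#' as its own bin. The Z-score of gene i is
#' \code{(v_i - mean(v_(-i))) / sd(v_(-i))} over its bin, with the gene
#' itself left out of both moments. Bins whose leave-one-out SD is zero (or
#' with fewer than 3 members) yield Z = 0 and are flagged in the
#' \code{degenerate_bins} attribute. With fewer than \code{bin_size} genes
#' a single bin is used, with a warning.
#'
#' @param values named numeric vector (gene -> value).
#' @param expression named numeric vector on the same genes (read counts).
#' @param bin_size genes per bin (default 300).
#' @return numeric vector of Z-scores in the input order, named.
#' @export
local_zscore <- function(values, expression, bin_size = 300L) {
  stopifnot(length(values) == length(expression))
  n <- length(values)
  if (n == 0) return(values)
  if (!is.null(names(values)) && !is.null(names(expression)))
    expression <- expression[names(values)]

  ord <- order(-expression, seq_len(n))   # descending; stable for ties
  if (n < bin_size) {
    warning("fewer genes (", n, ") than bin_size (", bin_size, "); using a single bin")
    bin_of <- rep(1L, n)
  } else {
    nb <- n %/% bin_size
    rem <- n - nb * bin_size
    bin_of <- rep(seq_len(nb), each = bin_size)
    if (rem > 0) {
      extra <- if (rem < bin_size / 2) nb else nb + 1L   # absorb small remainder
      bin_of <- c(bin_of, rep(extra, rem))
    }
  }

  z <- numeric(n)
  degenerate <- integer(0)
  for (b in unique(bin_of)) {
    idx <- ord[bin_of == b]
    v <- values[idx]
    m <- length(v)
    if (m < 3) { z[idx] <- 0; degenerate <- c(degenerate, b); next }
    s1 <- sum(v); s2 <- sum(v^2)
    mean_loo <- (s1 - v) / (m - 1)
    var_loo <- (s2 - v^2 - (m - 1) * mean_loo^2) / (m - 2)
    var_loo[var_loo < 0] <- 0   # guard FP cancellation
    zi <- (v - mean_loo) / sqrt(var_loo)
    bad <- !is.finite(zi)
    if (any(bad)) { zi[bad] <- 0; degenerate <- c(degenerate, b) }
    z[idx] <- zi
  }
  names(z) <- names(values)
  attr(z, "degenerate_bins") <- unique(degenerate)
  z
}
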