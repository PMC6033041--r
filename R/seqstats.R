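#' Per-column conservation profile
#'
#' For each alignment column, counts the ungapped sequences
#' (\code{n_ungapped}) and the sequences carrying the most frequent
#' residue (\code{n_modal}); ties for the modal residue are broken
#' alphabetically and flagged.
#'
#' @param aln A \code{numbered_alignment}.
#' @return A data frame with columns \code{position}, \code{n_ungapped},
#'   \code{n_modal}, \code{modal}, \code{tie}; the per-column residue
#'   count matrix is attached as attribute \code{"counts"}.
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "numbered_alignment"))
  if (nrow(aln$mat) == 0L || ncol(aln$mat) == 0L) {
    stop("empty alignment")
  }
  p <- ncol(aln$mat)
  counts <- vapply(seq_len(p), function(j) {
    tabulate(factor(aln$mat[, j], levels = AA_ALPHABET),
             nbins = length(AA_ALPHABET))
  }, integer(length(AA_ALPHABET)))
  rownames(counts) <- AA_ALPHABET
  n_ungapped <- colSums(counts)
  n_modal <- apply(counts, 2, max)
  modal <- AA_ALPHABET[apply(counts, 2, which.max)]  # first = alphabetical
  tie <- vapply(seq_len(p), function(j) {
    sum(counts[, j] == n_modal[j]) > 1L && n_modal[j] > 0L
  }, logical(1))
  modal[n_ungapped == 0L] <- NA_character_
  out <- data.frame(position = aln$positions,
                    n_ungapped = as.integer(n_ungapped),
                    n_modal = as.integer(n_modal),
                    modal = modal, tie = tie,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}

#' Per-column conservation level
#'
#' The conservation level used for cross-dataset significance testing:
#' the fraction of ungapped sequences carrying the modal residue,
#' \code{n_modal / n_ungapped} (\code{NA} at all-gap columns).
#'
#' @param profile Output of [conservation_profile()], or an alignment.
#' @return Numeric vector, one value per column.
#' @export
conservation_level <- function(profile) {
  if (inherits(profile, "numbered_alignment")) {
    profile <- conservation_profile(profile)
  }
  ifelse(profile$n_ungapped > 0L, profile$n_modal / profile$n_ungapped,
         NA_real_)
}

#' Sequence-logo matrix
#'
#' Per-column residue frequencies (over ungapped sequences), plus -- in
#' \code{"bits"} mode -- the information content
#' \eqn{I = \log_2 20 - H} with \eqn{H} the column Shannon entropy in
#' bits, optionally with the small-sample correction
#' \eqn{e_n = (s - 1) / (2 \ln 2 \, n)} (s = 20), clipped at 0.
#'
#' @param aln A \code{numbered_alignment}.
#' @param mode \code{"bits"} or \code{"frequency"}.
#' @param small_sample_correction Apply the small-sample correction in
#'   bits mode (default \code{FALSE}).
#' @return A \code{logo_matrix}: list with \code{freq} (P x 21 matrix
#'   over the amino-acid alphabet), \code{n_ungapped}, and (bits mode)
#'   \code{bits}.
#' @export
logo_matrix <- function(aln, mode = c("bits", "frequency"),
                        small_sample_correction = FALSE) {
  mode <- match.arg(mode)
  prof <- conservation_profile(aln)
  counts <- attr(prof, "counts")
  n <- prof$n_ungapped
  freq <- t(counts) / ifelse(n > 0L, n, 1L)
  freq[n == 0L, ] <- NA_real_
  out <- list(positions = prof$position, freq = freq,
              n_ungapped = n, mode = mode)
  if (mode == "bits") {
    h <- apply(freq, 1, function(f) {
      f <- f[!is.na(f) & f > 0]
      -sum(f * log2(f))
    })
    bits <- log2(20) - h
    if (isTRUE(small_sample_correction)) {
      bits <- bits - ifelse(n > 0L, (20 - 1) / (2 * log(2) * n), 0)
    }
    out$bits <- pmax(bits, 0)
    out$bits[n == 0L] <- NA_real_
  }
  structure(out, class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("logo_matrix (", x$mode, "): ", length(x$positions),
      " positions\n", sep = "")
  invisible(x)
}

#' Export a logo matrix as TSV
#'
#' @param logo A \code{logo_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = logo$positions,
                   n_ungapped = logo$n_ungapped,
                   round(logo$freq, 6), check.names = FALSE)
  if (!is.null(logo$bits)) df$bits <- round(logo$bits, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalized Hamming distance between two aligned rows
#'
#' Counts positions at which the rows differ, normalized to [0, 1].
#' Columns where both rows are gaps are excluded from numerator and
#' denominator; a gap against a residue counts as a difference. The
#' denominator is the number of non-(gap,gap) columns.
#'
#' @param a,b Character vectors (rows of an alignment).
#' @param positions Columns to compare (default all).
#' @return Fraction in [0, 1].
#' @export
hamming_norm <- function(a, b, positions = NULL) {
  if (length(a) != length(b)) stop("rows have different lengths")
  if (is.null(positions)) positions <- seq_along(a)
  if (length(positions) == 0L) stop("positions must be non-empty")
  a <- a[positions]
  b <- b[positions]
  keep <- !(a == GAP & b == GAP)
  if (!any(keep)) {
    stop("undefined distance: all compared columns are gap-gap")
  }
  sum(a[keep] != b[keep]) / sum(keep)
}

#' Pairwise normalized Hamming distance matrix
#'
#' @param aln A \code{numbered_alignment} or character matrix.
#' @param positions Columns to compare (default all).
#' @return A \code{pairwise_matrix}: \code{ids}, symmetric
#'   \code{values} with zero diagonal, and \code{summary} (mean, sd,
#'   max over the off-diagonal pairs). Pairs whose compared columns are
#'   all gap-gap get \code{NA} and are excluded from the summary.
#' @export
pairwise_hamming <- function(aln, positions = NULL) {
  mat <- if (inherits(aln, "numbered_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2L) stop("need at least two sequences")
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(hamming_norm(mat[i, ], mat[j, ], positions),
                    error = function(e) NA_real_)
      values[i, j] <- values[j, i] <- d
    }
  }
  ids <- if (!is.null(rownames(mat))) rownames(mat) else
    paste0("seq", seq_len(n))
  dimnames(values) <- list(ids, ids)
  new_pairwise_matrix(values, statistic = "hamming")
}

new_pairwise_matrix <- function(values, statistic, n_common = NULL) {
  off <- values[upper.tri(values)]
  off_ok <- off[!is.na(off)]
  summary <- list(mean = mean(off_ok), sd = stats::sd(off_ok),
                  max = if (length(off_ok)) max(off_ok) else NA_real_,
                  n_pairs = length(off_ok),
                  n_missing_pairs = sum(is.na(off)))
  out <- list(ids = rownames(values), values = values,
              statistic = statistic, summary = summary)
  if (!is.null(n_common)) {
    offc <- n_common[upper.tri(n_common)][!is.na(off)]
    out$n_common <- n_common
    out$summary$common_mean <- mean(offc)
    out$summary$common_sd <- stats::sd(offc)
  }
  structure(out, class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pairwise_matrix (%s): %d ids, mean %.4g +/- %.4g, max %.4g\n",
              x$statistic, length(x$ids), s$mean, s$sd, s$max))
  invisible(x)
}

#' Off-diagonal values of a pairwise matrix
#'
#' @param pm A \code{pairwise_matrix}.
#' @return Numeric vector of the N(N-1)/2 upper-triangle values
#'   (missing pairs dropped).
#' @export
pairwise_values <- function(pm) {
  v <- pm$values[upper.tri(pm$values)]
  v[!is.na(v)]
}

#' Subsample-based conservation significance
#'
#' Tests, per column, whether a target dataset's conservation level lies
#' outside \code{mean +/- sigma_mult * sd} of the level observed in
#' repeated random subsets of a (typically larger) pool alignment.
#' Draws are without replacement by default; with-replacement
#' resampling is available via \code{replace = TRUE}.
#'
#' @param target_profile [conservation_profile()] of the target
#'   alignment (or the alignment itself).
#' @param pool_aln Pool \code{numbered_alignment} with the same number
#'   of columns.
#' @param n_draws Number of subsets (default 6).
#' @param draw_size Sequences per subset (default 90).
#' @param sigma_mult Flag threshold in pool standard deviations
#'   (default 2).
#' @param replace Sample with replacement (default \code{FALSE}).
#' @param seed Optional integer seed (local to this call).
#' @return Data frame with columns \code{position}, \code{target_c},
#'   \code{pool_mean}, \code{pool_sigma}, \code{flag},
#'   \code{direction} ("more"/"less" conserved, \code{NA} if unflagged)
#'   and \code{degenerate} (pool sd was zero at that column).
#' @export
bootstrap_conservation_compare <- function(target_profile, pool_aln,
                                           n_draws = 6, draw_size = 90,
                                           sigma_mult = 2, replace = FALSE,
                                           seed = NULL) {
  if (n_draws < 2L) {
    stop("n_draws must be >= 2 (spread undefined from one draw)")
  }
  if (inherits(target_profile, "numbered_alignment")) {
    target_profile <- conservation_profile(target_profile)
  }
  stopifnot(inherits(pool_aln, "numbered_alignment"))
  n_pool <- nrow(pool_aln$mat)
  if (!replace && n_pool < draw_size) {
    stop("pool has ", n_pool, " sequences; need >= draw_size (", draw_size,
         ") for draws without replacement")
  }
  p <- ncol(pool_aln$mat)
  if (nrow(target_profile) != p) {
    stop("target and pool have different numbers of columns (",
         nrow(target_profile), " vs ", p, ")")
  }
  target_c <- conservation_level(target_profile)
  draws <- with_local_seed(seed, {
    vapply(seq_len(n_draws), function(k) {
      idx <- sample.int(n_pool, draw_size, replace = replace)
      sub <- new_alignment(ids = pool_aln$ids[idx],
                           positions = pool_aln$positions,
                           mat = pool_aln$mat[idx, , drop = FALSE])
      conservation_level(conservation_profile(sub))
    }, numeric(p))
  })
  pool_mean <- rowMeans(draws)
  pool_sigma <- apply(draws, 1, stats::sd)
  degenerate <- !is.na(pool_sigma) & pool_sigma == 0
  flag <- !is.na(target_c) & !is.na(pool_mean) &
    ifelse(degenerate,
           abs(target_c - pool_mean) > 1e-12,
           abs(target_c - pool_mean) > sigma_mult * pool_sigma)
  direction <- ifelse(flag,
                      ifelse(target_c > pool_mean, "more", "less"),
                      NA_character_)
  data.frame(position = target_profile$position,
             target_c = target_c, pool_mean = pool_mean,
             pool_sigma = pool_sigma, flag = flag,
             direction = direction, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

# Run code under a temporary RNG state; restores .Random.seed afterwards.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Unpaired two-sample t test
#'
#' Pooled-variance Student's t by default (two-tailed); Welch's variant
#' via \code{welch = TRUE}. Note that when applied to pairwise-distance
#' samples the observations are not independent, so the result is
#' descriptive.
#'
#' @param a,b Numeric samples.
#' @param welch Use Welch's unequal-variance t (default \code{FALSE}).
#' @return List with \code{t}, \code{p}, \code{df}.
#' @export
t_test_unpaired <- function(a, b, welch = FALSE) {
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Kullback-Leibler divergence between two length distributions
#'
#' \eqn{D(P\|Q) = \sum_x p(x) \log(p(x)/q(x))} over the union support.
#' A pseudocount, added to every bin of the union support before
#' renormalization, handles lengths present in one distribution only;
#' with \code{pseudocount = 0} and a support violation the divergence is
#' infinite (returned as \code{Inf} with a warning).
#'
#' @param p,q Named numeric vectors (names = integer lengths, values =
#'   probabilities or counts); normalized internally.
#' @param base Logarithm base, \code{"e"} (nats, default) or \code{"2"}
#'   (bits).
#' @param pseudocount Non-negative smoothing constant (default 0).
#' @return Non-negative scalar (0 iff P = Q after smoothing).
#' @export
kl_divergence <- function(p, q, base = c("e", "2"), pseudocount = 0) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  if (is.null(names(p))) names(p) <- seq_along(p)
  if (is.null(names(q))) names(q) <- seq_along(q)
  support <- sort(unique(as.numeric(c(names(p), names(q)))))
  pv <- p[as.character(support)]
  qv <- q[as.character(support)]
  pv[is.na(pv)] <- 0
  qv[is.na(qv)] <- 0
  pv <- pv + pseudocount
  qv <- qv + pseudocount
  if (sum(pv) <= 0 || sum(qv) <= 0) stop("distributions must have mass")
  pv <- pv / sum(pv)
  qv <- qv / sum(qv)
  lg <- if (base == "e") log else log2
  terms <- ifelse(pv > 0, pv * lg(pv / qv), 0)
  if (any(pv > 0 & qv == 0)) {
    warning("support violation with zero pseudocount: divergence is infinite")
    return(Inf)
  }
  max(sum(terms), 0)
}
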