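#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation of \code{Y} that minimizes
#' the RMSD to \code{X} over paired points. Reflections are excluded
#' (determinant +1), as required for chiral molecules. The transform
#' maps \code{Y} onto \code{X}: \code{Y \%*\% rotation + translation}.
#'
#' @param X,Y n x 3 coordinate matrices, paired row-wise (n >= 3).
#' @return List with \code{rotation} (3 x 3, det +1),
#'   \code{translation} (length-3), \code{rmsd} (Angstrom) and
#'   \code{degenerate} (\code{TRUE} if the point sets are essentially
#'   collinear/coincident, in which case the result is best-effort and
#'   a warning is issued).
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) {
    stop("X and Y must be matching n x 3 matrices")
  }
  n <- nrow(X)
  if (n < 3L) stop("insufficient points: need at least 3, got ", n)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("coordinates must be finite")
  }
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  # maximize tr(B R) over proper rotations, B = Xc' Yc
  B <- crossprod(Xc, Yc)
  sv <- svd(B)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (degenerate) {
    warning("degenerate geometry (collinear or coincident points); ",
            "superposition is best-effort")
  }
  t_vec <- cx - as.vector(cy %*% R)
  Yfit <- Y %*% R + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((X - Yfit)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       degenerate = degenerate)
}

#' Region-restricted pairwise RMSD matrix
#'
#' For every pair of coordinate sets: superpose (Kabsch) on the fit
#' positions where \emph{both} members have coordinates, then measure
#' RMSD over the measure positions where both have coordinates, under
#' that transform. Pairs with fewer than 3 common fit positions, or no
#' common measure position, are recorded as missing and excluded from
#' the summaries.
#'
#' @param coords List of P x 3 coordinate matrices (rows = alignment
#'   positions, \code{NA} rows = missing coordinates), all with the same
#'   P; names are used as ids.
#' @param fit_positions Alignment positions used for the superposition.
#' @param measure_positions Alignment positions over which the RMSD is
#'   computed (default: same as \code{fit_positions}).
#' @return A \code{pairwise_matrix} whose \code{summary} also reports
#'   the mean/sd of the per-pair common measure-position counts; field
#'   \code{missing_pairs} lists excluded pairs and the reason.
#' @export
pairwise_rmsd <- function(coords, fit_positions,
                          measure_positions = fit_positions) {
  n <- length(coords)
  if (n < 2L) stop("need at least two coordinate sets")
  ids <- if (!is.null(names(coords))) names(coords) else
    paste0("s", seq_len(n))
  p <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == p &&
                 ncol(m) == 3L, logical(1))
  if (!all(ok)) stop("all coordinate sets must be P x 3 matrices, equal P")
  fit_positions <- as.integer(fit_positions)
  measure_positions <- as.integer(measure_positions)
  if (any(c(fit_positions, measure_positions) < 1L) ||
      any(c(fit_positions, measure_positions) > p)) {
    stop("positions out of range 1..", p)
  }
  present <- vapply(coords, function(m) stats::complete.cases(m), logical(p))
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  n_common <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  missing_pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- present[, i] & present[, j]
      fit <- fit_positions[both[fit_positions]]
      meas <- measure_positions[both[measure_positions]]
      if (length(fit) < 3L || length(meas) == 0L) {
        values[i, j] <- values[j, i] <- NA_real_
        missing_pairs[[length(missing_pairs) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], n_fit = length(fit),
          n_measure = length(meas), stringsAsFactors = FALSE)
        next
      }
      kb <- kabsch(coords[[i]][fit, , drop = FALSE],
                   coords[[j]][fit, , drop = FALSE])
      Yt <- coords[[j]][meas, , drop = FALSE] %*% kb$rotation +
        matrix(kb$translation, length(meas), 3, byrow = TRUE)
      dev2 <- rowSums((coords[[i]][meas, , drop = FALSE] - Yt)^2)
      values[i, j] <- values[j, i] <- sqrt(mean(dev2))
      n_common[i, j] <- n_common[j, i] <- length(meas)
    }
  }
  out <- new_pairwise_matrix(values, statistic = "rmsd",
                             n_common = n_common)
  out$missing_pairs <- if (length(missing_pairs)) {
    do.call(rbind, missing_pairs)
  } else {
    data.frame(id_a = character(), id_b = character(),
               n_fit = integer(), n_measure = integer(),
               stringsAsFactors = FALSE)
  }
  if (nrow(out$missing_pairs) > 0L) {
    message("pairwise_rmsd: excluded ", nrow(out$missing_pairs),
            " pair(s) with <3 common fit positions or no common ",
            "measure position")
  }
  out
}

#' Per-position mean deviation profile after superposition
#'
#' For each measure position, the mean over structure pairs of the
#' inter-C-alpha distance after fitting each pair on the fit positions.
#' Positions covered by no pair are \code{NA}.
#'
#' @inheritParams pairwise_rmsd
#' @return Data frame with columns \code{position}, \code{mean_dev},
#'   \code{n_pairs}.
#' @export
per_position_rmsd <- function(coords, fit_positions,
                              measure_positions = fit_positions) {
  n <- length(coords)
  if (n < 2L) stop("need at least two coordinate sets")
  p <- nrow(coords[[1]])
  fit_positions <- as.integer(fit_positions)
  measure_positions <- as.integer(measure_positions)
  present <- vapply(coords, function(m) stats::complete.cases(m), logical(p))
  acc <- numeric(length(measure_positions))
  cnt <- integer(length(measure_positions))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- present[, i] & present[, j]
      fit <- fit_positions[both[fit_positions]]
      if (length(fit) < 3L) next
      kb <- kabsch(coords[[i]][fit, , drop = FALSE],
                   coords[[j]][fit, , drop = FALSE])
      covered <- which(both[measure_positions])
      if (length(covered) == 0L) next
      meas <- measure_positions[covered]
      Yt <- coords[[j]][meas, , drop = FALSE] %*% kb$rotation +
        matrix(kb$translation, length(meas), 3, byrow = TRUE)
      d <- sqrt(rowSums((coords[[i]][meas, , drop = FALSE] - Yt)^2))
      acc[covered] <- acc[covered] + d
      cnt[covered] <- cnt[covered] + 1L
    }
  }
  data.frame(position = measure_positions,
             mean_dev = ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_),
             n_pairs = cnt)
}

#' Build alignment-position coordinate sets from complex records
#'
#' Maps each binder residue to its scheme position through the record's
#' numbering table (the k-th numbered position corresponds to the k-th
#' residue in chain order) and collects C-alpha coordinates into a
#' P x 3 matrix with \code{NA} rows where coordinates are absent.
#'
#' @param records List of \code{complex_record}s.
#' @param numbering List of \code{numbered_sequence}s, parallel to
#'   \code{records}.
#' @param scheme_length Total number of scheme positions.
#' @return Named list of P x 3 matrices.
#' @export
coord_sets <- function(records, numbering, scheme_length) {
  stopifnot(length(records) == length(numbering))
  out <- lapply(seq_along(records), function(i) {
    dom <- records[[i]]$binder
    num <- numbering[[i]]
    ca <- domain_ca(dom)
    m <- matrix(NA_real_, scheme_length, 3)
    k <- min(nrow(ca), length(num$positions))
    if (nrow(ca) != length(num$positions)) {
      message("coord_sets: record ", records[[i]]$id, " has ", nrow(ca),
              " residues but ", length(num$positions),
              " numbered positions; using the first ", k)
    }
    m[num$positions[seq_len(k)], ] <- ca[seq_len(k), ]
    m
  })
  names(out) <- vapply(records, `[[`, character(1), "id")
  out
}
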