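#' Read one per-residue numbering table
#'
#' A numbering table is a CSV with columns \code{scheme_position},
#' \code{insertion_code}, \code{residue}, listing (in chain order) the
#' scheme position of every residue of one domain. Fixed-length schemes
#' (AHo-style) use no insertion codes, so the insertion column must be
#' empty. An optional comment line \code{# scheme_length: N} declares
#' the total number of scheme positions.
#'
#' @param path CSV path.
#' @param id Record identifier (default: file name without extension).
#' @return A \code{numbered_sequence}: \code{id}, \code{positions}
#'   (strictly increasing integers), \code{residues} (one-letter codes),
#'   \code{scheme_length} (integer or \code{NA}).
#' @export
read_numbering_csv <- function(path, id = NULL) {
  if (!file.exists(path)) stop("numbering table not found: ", path)
  raw <- readLines(path)
  scheme_length <- NA_integer_
  meta <- grep("^#", raw, value = TRUE)
  m <- regmatches(meta, regexec("scheme_length\\s*[:=]\\s*([0-9]+)", meta))
  m <- Filter(function(x) length(x) == 2L, m)
  if (length(m) > 0L) scheme_length <- as.integer(m[[1]][2])
  tab <- utils::read.csv(text = raw, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c("integer", "character", "character"))
  needed <- c("scheme_position", "insertion_code", "residue")
  if (!all(needed %in% names(tab))) {
    stop("numbering table '", path, "' must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (any(nzchar(trimws(tab$insertion_code)))) {
    stop("malformed numbering in '", path,
         "': insertion codes are not allowed in a fixed-length scheme")
  }
  if (anyDuplicated(tab$scheme_position)) {
    stop("malformed numbering in '", path, "': duplicate scheme position(s) ",
         paste(unique(tab$scheme_position[duplicated(tab$scheme_position)]),
               collapse = ","))
  }
  res <- toupper(trimws(tab$residue))
  bad <- !(res %in% AA_ALPHABET)
  if (any(bad)) {
    stop("alphabet error in '", path, "': invalid residue letter(s) ",
         paste(unique(res[bad]), collapse = ","))
  }
  ord <- order(tab$scheme_position)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(tab) == 0L) {
    warning("numbering table '", path, "' is empty; row will be all gaps")
  }
  structure(
    list(id = id,
         positions = as.integer(tab$scheme_position[ord]),
         residues = res[ord],
         scheme_length = scheme_length),
    class = "numbered_sequence"
  )
}

#' Load numbering tables into a scheme-numbered alignment
#'
#' Residues at scheme positions not listed in a table become gaps. The
#' scheme length is taken from \code{scheme_length} if given, otherwise
#' from the tables' declared lengths (which must agree), otherwise from
#' the maximum listed position.
#'
#' @param paths Character vector of numbering CSV paths, or a list of
#'   \code{numbered_sequence} objects.
#' @param scheme_length Total number of scheme positions (optional).
#' @return A \code{numbered_alignment}: \code{ids}, \code{positions}
#'   (scheme positions of the columns), \code{mat} (N x P character
#'   matrix with \code{"-"} gaps); \code{reduced} is \code{FALSE}.
#' @export
load_numbering_tables <- function(paths, scheme_length = NULL) {
  seqs <- if (is.list(paths) && length(paths) > 0L &&
              inherits(paths[[1]], "numbered_sequence")) {
    paths
  } else {
    lapply(paths, read_numbering_csv)
  }
  if (length(seqs) == 0L) stop("no numbering tables given")
  declared <- unique(stats::na.omit(vapply(seqs, `[[`, integer(1),
                                           "scheme_length")))
  if (length(declared) > 1L) {
    stop("numbering tables declare different scheme lengths: ",
         paste(declared, collapse = " vs "))
  }
  if (is.null(scheme_length)) {
    scheme_length <- if (length(declared) == 1L) declared else
      max(vapply(seqs, function(s) {
        if (length(s$positions)) max(s$positions) else 0L
      }, integer(1)))
  }
  scheme_length <- as.integer(scheme_length)
  toohigh <- Filter(function(s) length(s$positions) &&
                      max(s$positions) > scheme_length, seqs)
  if (length(toohigh) > 0L) {
    stop("numbering table '", toohigh[[1]]$id, "' lists position ",
         max(toohigh[[1]]$positions), " beyond scheme length ", scheme_length)
  }
  mat <- matrix(GAP, nrow = length(seqs), ncol = scheme_length)
  for (i in seq_along(seqs)) {
    mat[i, seqs[[i]]$positions] <- seqs[[i]]$residues
  }
  rownames(mat) <- vapply(seqs, `[[`, character(1), "id")
  new_alignment(ids = rownames(mat), positions = seq_len(scheme_length),
                mat = mat)
}

new_alignment <- function(ids, positions, mat, reduced = FALSE,
                          full_positions = NULL, retained = NULL,
                          gap_threshold = NA_real_) {
  structure(
    list(ids = ids, positions = as.integer(positions), mat = mat,
         reduced = reduced, full_positions = full_positions,
         retained = retained, gap_threshold = gap_threshold),
    class = "numbered_alignment"
  )
}

#' Build an alignment directly from a character matrix
#'
#' Convenience constructor for tests and small examples.
#'
#' @param mat N x P character matrix of residues and \code{"-"} gaps.
#' @param ids Optional row ids.
#' @return A \code{numbered_alignment}.
#' @export
alignment_from_matrix <- function(mat, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(mat))) rownames(mat) else
      paste0("seq", seq_len(nrow(mat)))
  }
  rownames(mat) <- ids
  new_alignment(ids = ids, positions = seq_len(ncol(mat)), mat = mat)
}

#' @export
print.numbered_alignment <- function(x, ...) {
  cat("numbered_alignment:", nrow(x$mat), "sequences x", ncol(x$mat),
      if (isTRUE(x$reduced)) "reduced positions\n" else "scheme positions\n")
  invisible(x)
}

#' Remove mostly-gap columns from an alignment
#'
#' A column is removed iff its gap fraction strictly exceeds
#' \code{gap_threshold} (the ">85% gaps" rule at the default). The
#' operation is idempotent and records the reduced-to-full position
#' maps.
#'
#' @param aln A \code{numbered_alignment}.
#' @param gap_threshold Gap fraction above which a column is dropped
#'   (default 0.85).
#' @return A reduced \code{numbered_alignment}; \code{positions} are
#'   renumbered 1..P_reduced, \code{full_positions} holds the original
#'   scheme position of each retained column and \code{retained} the
#'   logical mask over the input columns.
#' @export
reduce_alignment <- function(aln, gap_threshold = 0.85) {
  stopifnot(inherits(aln, "numbered_alignment"))
  if (!is.numeric(gap_threshold) || length(gap_threshold) != 1L ||
      is.na(gap_threshold) || gap_threshold < 0 || gap_threshold > 1) {
    stop("gap_threshold must be a single number in [0, 1]")
  }
  n <- nrow(aln$mat)
  if (n < 1L) stop("alignment has no sequences")
  gap_frac <- colMeans(aln$mat == GAP)
  keep <- !(gap_frac > gap_threshold)
  full_positions <- if (isTRUE(aln$reduced)) aln$full_positions else
    aln$positions
  new_alignment(
    ids = aln$ids,
    positions = seq_len(sum(keep)),
    mat = aln$mat[, keep, drop = FALSE],
    reduced = TRUE,
    full_positions = full_positions[keep],
    retained = keep,
    gap_threshold = gap_threshold
  )
}

#' Map reduced positions to full scheme positions
#'
#' @param aln A reduced \code{numbered_alignment}.
#' @param positions Reduced position indices (default all).
#' @return Integer vector of full scheme positions.
#' @export
reduced_to_full <- function(aln, positions = NULL) {
  stopifnot(isTRUE(aln$reduced))
  if (is.null(positions)) positions <- aln$positions
  aln$full_positions[positions]
}

#' Map full scheme positions to reduced positions
#'
#' @param aln A reduced \code{numbered_alignment}.
#' @param positions Full scheme positions.
#' @return Integer vector of reduced positions (\code{NA} where the
#'   column was removed).
#' @export
full_to_reduced <- function(aln, positions) {
  stopifnot(isTRUE(aln$reduced))
  match(positions, aln$full_positions)
}

#' Named framework/loop region map over a reduced alignment
#'
#' Defaults reproduce the standard 126-position reduced map with
#' hypervariable loops H1 = 26--35, H2 = 50--59, H3 = 98--116; the four
#' framework regions are the complementary spans (87 positions at the
#' defaults). Alternative spans may be supplied.
#'
#' @param p Number of (reduced) alignment positions (default 126).
#' @param h1,h2,h3 Integer vectors of loop positions (contiguous spans).
#' @return A \code{region_map}: data frame with columns \code{position}
#'   and \code{region} (FR1, H1, FR2, H2, FR3, H3, FR4).
#' @export
region_map <- function(p = 126L, h1 = 26:35, h2 = 50:59, h3 = 98:116) {
  p <- as.integer(p)
  loops <- list(H1 = as.integer(h1), H2 = as.integer(h2), H3 = as.integer(h3))
  for (nm in names(loops)) {
    lp <- loops[[nm]]
    if (length(lp) == 0L || any(lp < 1L | lp > p) ||
        !identical(lp, seq(min(lp), max(lp)))) {
      stop("loop ", nm, " must be a contiguous span within 1..", p)
    }
  }
  all_loop <- unlist(loops, use.names = FALSE)
  if (anyDuplicated(all_loop)) stop("loop spans overlap")
  if (!(max(loops$H1) < min(loops$H2) && max(loops$H2) < min(loops$H3))) {
    stop("loop spans must be ordered H1 < H2 < H3")
  }
  region <- character(p)
  region[loops$H1] <- "H1"
  region[loops$H2] <- "H2"
  region[loops$H3] <- "H3"
  region[seq_len(min(loops$H1) - 1L)] <- "FR1"
  region[(max(loops$H1) + 1L):(min(loops$H2) - 1L)] <- "FR2"
  region[(max(loops$H2) + 1L):(min(loops$H3) - 1L)] <- "FR3"
  if (max(loops$H3) < p) region[(max(loops$H3) + 1L):p] <- "FR4"
  region_map_from_labels(region)
}

#' Region map from per-position labels
#'
#' @param labels Character vector of region names (FR1, H1, FR2, H2,
#'   FR3, H3, FR4), one per alignment position.
#' @return A \code{region_map}.
#' @export
region_map_from_labels <- function(labels) {
  valid <- c("FR1", "H1", "FR2", "H2", "FR3", "H3", "FR4")
  if (!all(labels %in% valid)) {
    stop("unknown region label(s): ",
         paste(unique(setdiff(labels, valid)), collapse = ","))
  }
  structure(
    data.frame(position = seq_along(labels), region = labels,
               stringsAsFactors = FALSE),
    class = c("region_map", "data.frame")
  )
}

#' Positions of named regions
#'
#' @param map A \code{region_map}.
#' @param names Region names; \code{"FR"} expands to FR1--FR4 and
#'   \code{"loops"} to H1--H3.
#' @return Sorted integer vector of positions.
#' @export
region_positions <- function(map, names) {
  stopifnot(inherits(map, "region_map"))
  names <- unlist(lapply(names, function(nm) {
    switch(nm,
           FR = c("FR1", "FR2", "FR3", "FR4"),
           loops = c("H1", "H2", "H3"),
           nm)
  }))
  unknown <- setdiff(names, unique(map$region))
  if (length(unknown) > 0L) {
    stop("unknown region name(s): ", paste(unknown, collapse = ","))
  }
  sort(map$position[map$region %in% names])
}

#' Full-scheme span of a loop, including removed central columns
#'
#' Loop-length and loop-Hamming analyses run on the unreduced alignment
#' so that the low-occupancy central columns count. The full span of a
#' loop runs from the full-scheme image of its first retained column to
#' that of its last.
#'
#' @param aln A reduced \code{numbered_alignment}.
#' @param map \code{region_map} over the reduced positions.
#' @param name Loop name ("H1", "H2", "H3").
#' @return Integer vector of full scheme positions.
#' @export
full_region_span <- function(aln, map, name) {
  pos <- region_positions(map, name)
  fp <- reduced_to_full(aln, pos)
  seq(min(fp), max(fp))
}
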