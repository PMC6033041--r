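#' Parse a coordinate file into per-chain domain structures
#'
#' Reads a PDB or mmCIF file and returns, for every polymer chain, its
#' one-letter sequence and per-residue heavy-atom records. Hydrogens are
#' excluded everywhere; when alternate conformers are present the
#' highest-occupancy conformer is kept (ties resolved in favour of
#' conformer "A"). Nonstandard amino acids are mapped to \code{"X"}.
#' Residues are keyed by sequential index in chain order; author residue
#' numbers are retained as metadata.
#'
#' @param path Path to a structure file.
#' @param format One of \code{"auto"} (decide from the file extension),
#'   \code{"pdb"} or \code{"cif"}.
#' @return A named list (one element per polymer chain) of
#'   \code{domain_structure} objects with fields \code{sequence}
#'   (one-letter string), \code{aa} (per-residue letters), \code{atoms}
#'   (data frame of heavy atoms: \code{res_index}, \code{elety},
#'   \code{elesy}, \code{resno}, \code{x}, \code{y}, \code{z}),
#'   \code{has_ca} (per-residue C-alpha presence mask) and \code{resno}
#'   (author numbering).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop("could not parse '", path, "' as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  atoms <- pdb$atom
  atoms <- atoms[is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z), ]
  atoms <- drop_hydrogens(atoms)
  atoms <- resolve_altloc(atoms)

  poly <- atoms[atoms$type == "ATOM", ]
  if (nrow(poly) == 0L) {
    stop("no polymer chain found in '", path, "'")
  }
  chains <- unique(poly$chain)
  out <- lapply(chains, function(ch) {
    build_domain_structure(poly[poly$chain == ch, ])
  })
  names(out) <- chains
  out
}

drop_hydrogens <- function(atoms) {
  elesy <- toupper(trimws(ifelse(is.na(atoms$elesy), "", atoms$elesy)))
  is_h <- elesy %in% c("H", "D")
  # fall back on the atom name when the element column is absent
  noel <- elesy == ""
  if (any(noel)) {
    nm <- toupper(trimws(atoms$elety[noel]))
    is_h[noel] <- grepl("^[0-9]*[HD]", nm)
  }
  atoms[!is_h, , drop = FALSE]
}

# Keep one conformer per (chain, residue, atom name): highest occupancy,
# ties broken in favour of conformer 'A' (then alphabetically).
resolve_altloc <- function(atoms) {
  alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  if (all(alt == "")) {
    return(atoms)
  }
  occ <- ifelse(is.na(atoms$o), 1, atoms$o)
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$elety, sep = "\r")
  ord <- order(key, -occ, alt != "A", alt)
  atoms <- atoms[ord, ]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

build_domain_structure <- function(chain_atoms) {
  ins <- ifelse(is.na(chain_atoms$insert), "", chain_atoms$insert)
  rkey <- paste(chain_atoms$resno, ins, sep = "\r")
  res_index <- match(rkey, unique(rkey))
  first <- !duplicated(rkey)
  resid3 <- chain_atoms$resid[first]
  # only the 20 standard residues map to letters; modified/nonstandard
  # residues (SEP, MSE, ...) become 'X'
  standard3 <- vapply(AA20, bio3d::aa123, character(1))
  aa <- rep("X", length(resid3))
  std <- resid3 %in% standard3
  aa[std] <- suppressWarnings(bio3d::aa321(resid3[std]))
  atoms <- data.frame(
    res_index = res_index,
    elety = chain_atoms$elety,
    elesy = toupper(trimws(ifelse(is.na(chain_atoms$elesy), "",
                                  chain_atoms$elesy))),
    resno = chain_atoms$resno,
    x = chain_atoms$x, y = chain_atoms$y, z = chain_atoms$z,
    stringsAsFactors = FALSE
  )
  has_ca <- vapply(seq_along(aa), function(i) {
    any(atoms$res_index == i & atoms$elety == "CA")
  }, logical(1))
  structure(
    list(
      sequence = paste(aa, collapse = ""),
      aa = aa,
      atoms = atoms,
      has_ca = has_ca,
      resno = chain_atoms$resno[first],
      insert = ins[first]
    ),
    class = "domain_structure"
  )
}

#' @export
print.domain_structure <- function(x, ...) {
  cat("domain_structure:", nchar(x$sequence), "residues,",
      nrow(x$atoms), "heavy atoms,",
      sum(!x$has_ca), "residues without C-alpha\n")
  invisible(x)
}

#' C-alpha coordinates of a domain structure
#'
#' @param domain A \code{domain_structure}.
#' @return An n x 3 matrix with one row per residue; rows are \code{NA}
#'   for residues lacking a C-alpha.
#' @export
domain_ca <- function(domain) {
  n <- length(domain$aa)
  xyz <- matrix(NA_real_, n, 3)
  ca <- domain$atoms[domain$atoms$elety == "CA", ]
  xyz[ca$res_index, ] <- as.matrix(ca[, c("x", "y", "z")])
  xyz
}

#' Assemble a complex record from a manifest row
#'
#' Combines the binder chain with the heavy atoms of the listed antigen
#' chains. A bound row must name at least one antigen chain present in
#' the file; an apo row has an empty antigen set.
#'
#' @param row A list/one-row data frame with fields \code{file},
#'   \code{binder_chain}, \code{antigen_chains} (comma-separated, empty
#'   for apo), \code{species}, \code{state} ("bound" or "apo").
#' @param chains Parsed chain map from [parse_structure()].
#' @return A \code{complex_record}: \code{binder} (domain_structure),
#'   \code{antigen} (heavy-atom data frame), \code{species},
#'   \code{state}, \code{id}.
#' @export
build_complex <- function(row, chains) {
  state <- match.arg(as.character(row$state), c("bound", "apo"))
  if (!row$binder_chain %in% names(chains)) {
    stop("manifest error: binder chain '", row$binder_chain,
         "' not present in '", row$file, "'")
  }
  ag_ids <- parse_chain_list(row$antigen_chains)
  if (state == "bound" && length(ag_ids) == 0L) {
    stop("manifest error: bound row for '", row$file,
         "' lists no antigen chains")
  }
  if (state == "apo" && length(ag_ids) > 0L) {
    stop("manifest error: apo row for '", row$file,
         "' lists antigen chains")
  }
  missing_ag <- setdiff(ag_ids, names(chains))
  if (length(missing_ag) > 0L) {
    stop("manifest error: antigen chain(s) ",
         paste(missing_ag, collapse = ","),
         " not present in '", row$file, "'")
  }
  antigen <- do.call(rbind, lapply(ag_ids, function(ch) {
    a <- chains[[ch]]$atoms
    if (nrow(a) > 0L) a$chain <- ch
    a
  }))
  if (is.null(antigen)) {
    antigen <- data.frame(res_index = integer(), elety = character(),
                          elesy = character(), resno = integer(),
                          x = numeric(), y = numeric(), z = numeric(),
                          chain = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(
      binder = chains[[row$binder_chain]],
      antigen = antigen,
      species = as.character(row$species),
      state = state,
      id = paste0(sub("\\.(pdb|cif|mmcif)$", "",
                      basename(as.character(row$file)), ignore.case = TRUE),
                  "_", row$binder_chain)
    ),
    class = "complex_record"
  )
}

parse_chain_list <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L || is.na(x) || trimws(x) == "") {
    return(character())
  }
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' @export
print.complex_record <- function(x, ...) {
  cat("complex_record", x$id, "(", x$state, "):",
      nchar(x$binder$sequence), "binder residues,",
      nrow(x$antigen), "antigen atoms\n")
  invisible(x)
}

#' Load a dataset of complexes from a manifest
#'
#' The manifest is a TSV with header
#' \code{file binder_chain antigen_chains species state}; file paths are
#' resolved relative to the manifest's directory. Row-level problems are
#' collected and reported together. With \code{dedup = TRUE} records
#' whose binder sequence is identical to an earlier record are removed
#' (the removal is reported via \code{message()}).
#'
#' @param manifest_path Path to the manifest TSV.
#' @param dedup Remove later records with a binder sequence identical to
#'   an earlier one (default \code{TRUE}).
#' @return A list of \code{complex_record}s.
#' @export
load_dataset <- function(manifest_path, dedup = TRUE) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("file", "binder_chain", "antigen_chains", "species", "state")
  if (!all(needed %in% names(man))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  }
  key <- paste(man$file, man$binder_chain)
  if (anyDuplicated(key)) {
    stop("manifest error: duplicate (file, binder_chain) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  base <- dirname(manifest_path)
  records <- vector("list", nrow(man))
  errors <- character()
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    fpath <- row$file
    if (!file.exists(fpath)) fpath <- file.path(base, row$file)
    res <- tryCatch({
      chains <- if (exists(fpath, envir = cache)) {
        get(fpath, envir = cache)
      } else {
        ch <- parse_structure(fpath)
        assign(fpath, ch, envir = cache)
        ch
      }
      row$file <- fpath
      build_complex(row, chains)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("row ", i, " (", row$file, "): ",
                                 conditionMessage(res)))
    } else {
      records[[i]] <- res
    }
  }
  if (length(errors) > 0L) {
    stop("manifest loading failed:\n  ", paste(errors, collapse = "\n  "))
  }
  if (isTRUE(dedup)) {
    seqs <- vapply(records, function(r) r$binder$sequence, character(1))
    dup <- duplicated(seqs)
    if (any(dup)) {
      message("load_dataset: removed ", sum(dup),
              " record(s) with duplicate binder sequence: ",
              paste(vapply(records[dup], `[[`, character(1), "id"),
                    collapse = ", "))
      records <- records[!dup]
    }
  }
  records
}

#' Write a domain structure as a PDB file
#'
#' Intended for round-tripping and for emitting synthetic families;
#' coordinates are written at 3-decimal precision (the PDB fixed-width
#' limit).
#'
#' @param domain A \code{domain_structure}.
#' @param path Output file path.
#' @param chain Chain identifier to write (default "A").
#' @param extra Optional additional atom data frame (same columns as
#'   \code{domain$atoms} plus \code{chain} and a \code{resid} column),
#'   e.g. an antigen pseudo-chain; written as ATOM records after a TER.
#' @return \code{path}, invisibly.
#' @export
write_domain_pdb <- function(domain, path, chain = "A", extra = NULL) {
  aa3 <- vapply(domain$aa, function(a) {
    if (a %in% AA20) bio3d::aa123(a) else "UNK"
  }, character(1))
  lines <- character()
  serial <- 0L
  fmt_atom <- function(serial, name, resid, chain, resno, x, y, z, elesy) {
    nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, nm, resid, chain, resno, x, y, z, 1, 0, elesy)
  }
  for (i in seq_len(nrow(domain$atoms))) {
    a <- domain$atoms[i, ]
    serial <- serial + 1L
    lines <- c(lines, fmt_atom(serial, a$elety, aa3[a$res_index], chain,
                               domain$resno[a$res_index],
                               a$x, a$y, a$z,
                               if (nzchar(a$elesy)) a$elesy else
                                 substr(a$elety, 1, 1)))
  }
  lines <- c(lines, "TER")
  if (!is.null(extra) && nrow(extra) > 0L) {
    for (i in seq_len(nrow(extra))) {
      a <- extra[i, ]
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, a$elety, a$resid, a$chain,
                                 a$resno, a$x, a$y, a$z,
                                 if (nzchar(a$elesy)) a$elesy else
                                   substr(a$elety, 1, 1)))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
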