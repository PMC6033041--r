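#' Full-scheme layout for synthetic immunoglobulin-like families
#'
#' Defines a fixed-length numbering scheme: four framework blocks (87
#' positions at the defaults) interleaved with three loop spans whose
#' capacities exceed the typical loop lengths, so that central loop
#' columns are mostly gaps -- the structure an AHo-style scheme
#' produces, where loop residues fill each span symmetrically from the
#' ends toward the center.
#'
#' @param fr_sizes Lengths of FR1--FR4 (default c(25, 14, 38, 10)).
#' @param loop_caps Span capacities of H1--H3 (default c(14, 14, 31)).
#' @return A \code{scheme_layout}: \code{labels} (region name per full
#'   scheme position), \code{spans} (named list of position vectors),
#'   \code{length}.
#' @export
scheme_layout <- function(fr_sizes = c(25L, 14L, 38L, 10L),
                          loop_caps = c(H1 = 14L, H2 = 14L, H3 = 31L)) {
  sizes <- c(FR1 = fr_sizes[1], H1 = loop_caps[["H1"]],
             FR2 = fr_sizes[2], H2 = loop_caps[["H2"]],
             FR3 = fr_sizes[3], H3 = loop_caps[["H3"]],
             FR4 = fr_sizes[4])
  labels <- rep(names(sizes), times = sizes)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  spans <- Map(seq, starts, ends)
  names(spans) <- names(sizes)
  structure(list(labels = labels, spans = spans,
                 length = sum(sizes)),
            class = "scheme_layout")
}

#' Idealized C-alpha scaffold trace
#'
#' A uniform helical C-alpha trace through every full-scheme position,
#' with consecutive C-alpha distances of \code{step} (3.8 Angstrom
#' default, the trans peptide C-alpha spacing). Loop spans are
#' geometrically contiguous with their flanking framework anchors by
#' construction. Deterministic.
#'
#' @param layout A \code{scheme_layout}.
#' @param radius Helix radius in Angstrom (default 9).
#' @param step Consecutive C-alpha distance in Angstrom (default 3.8).
#' @return An L x 3 coordinate matrix (L = layout length).
#' @export
make_scaffold <- function(layout = scheme_layout(), radius = 9,
                          step = 3.8) {
  n <- layout$length
  dtheta <- 0.35
  chord_xy <- 2 * radius * sin(dtheta / 2)
  if (chord_xy >= step) stop("helix radius too large for the given step")
  dz <- sqrt(step^2 - chord_xy^2)
  i <- seq_len(n) - 1L
  cbind(x = radius * cos(i * dtheta),
        y = radius * sin(i * dtheta),
        z = i * dz)
}

#' Discretized normal length distribution
#'
#' @param mean,sd Mean and standard deviation of the underlying normal.
#' @param min,max Integer support bounds (inclusive).
#' @return Named probability vector over \code{min:max}.
#' @export
discrete_normal_lengths <- function(mean, sd, min, max) {
  support <- min:max
  p <- stats::dnorm(support, mean, sd)
  p <- p / sum(p)
  names(p) <- support
  p
}

#' Specification of a synthetic immunoglobulin-like family
#'
#' Collects every ground-truth parameter of a generated family: family
#' size, per-region coordinate noise, loop-length distributions,
#' per-region sequence conservation (probability of the modal residue
#' at each column), designated paratope positions with their designed
#' contact propensities, the fraction of residues with missing
#' C-alpha coordinates, and the seed.
#'
#' @param name Family name (used in file names).
#' @param n Number of structures.
#' @param state \code{"bound"} (antigen pseudo-chain emitted) or
#'   \code{"apo"}.
#' @param fr_sigma Framework coordinate noise sigma, Angstrom.
#' @param loop_sigma Named numeric (H1, H2, H3) loop noise sigmas.
#' @param loop_lengths Named list (H1, H2, H3) of named probability
#'   vectors over integer lengths.
#' @param fr_conservation Modal-residue probability at framework
#'   columns.
#' @param loop_conservation Named numeric (H1, H2, H3) modal-residue
#'   probability at loop columns.
#' @param paratope_positions Integer vector of designated full-scheme
#'   paratope positions (must be occupied in every structure).
#' @param paratope_propensity Designed contact propensities, parallel
#'   to \code{paratope_positions}.
#' @param miss_frac Fraction of residues emitted without a C-alpha
#'   (they keep a side-chain pseudo-atom; default 0.02).
#' @param species Character vector of species names to sample from.
#' @param species_prob Sampling weights for \code{species}.
#' @param seed Integer seed; all randomness of the family flows from
#'   it.
#' @param layout A \code{scheme_layout}.
#' @return A \code{family_spec} list.
#' @export
family_spec <- function(name = "synthetic",
                        n = 90L,
                        state = c("bound", "apo"),
                        fr_sigma = 0.4,
                        loop_sigma = c(H1 = 1.0, H2 = 0.8, H3 = 2.0),
                        loop_lengths = list(
                          H1 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
                          H2 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
                          H3 = discrete_normal_lengths(15, 4, 8, 29)),
                        fr_conservation = 0.8,
                        loop_conservation = c(H1 = 0.55, H2 = 0.55,
                                              H3 = 0.3),
                        paratope_positions = integer(),
                        paratope_propensity = numeric(),
                        miss_frac = 0.02,
                        species = c("llama", "camel", "alpaca"),
                        species_prob = c(60, 24, 6),
                        seed = 1L,
                        layout = scheme_layout()) {
  state <- match.arg(state)
  stopifnot(fr_sigma >= 0, all(loop_sigma >= 0),
            fr_conservation >= 0, fr_conservation <= 1,
            all(loop_conservation >= 0), all(loop_conservation <= 1),
            miss_frac >= 0, miss_frac < 1,
            length(paratope_positions) == length(paratope_propensity),
            all(paratope_propensity >= 0), all(paratope_propensity <= 1))
  if (length(paratope_positions) > 0L &&
      (any(paratope_positions < 1L) ||
       any(paratope_positions > layout$length))) {
    stop("designated paratope positions must lie within the scheme")
  }
  for (nm in c("H1", "H2", "H3")) {
    ll <- loop_lengths[[nm]]
    if (max(as.integer(names(ll))) > length(layout$spans[[nm]])) {
      stop("loop ", nm, " length distribution exceeds span capacity ",
           length(layout$spans[[nm]]))
    }
  }
  structure(list(name = name, n = as.integer(n), state = state,
                 fr_sigma = fr_sigma, loop_sigma = loop_sigma,
                 loop_lengths = loop_lengths,
                 fr_conservation = fr_conservation,
                 loop_conservation = loop_conservation,
                 paratope_positions = as.integer(paratope_positions),
                 paratope_propensity = paratope_propensity,
                 miss_frac = miss_frac,
                 species = species, species_prob = species_prob,
                 seed = as.integer(seed), layout = layout),
            class = "family_spec")
}

# Columns of a loop span occupied by a loop of the given length:
# symmetric fill from the span ends toward the center.
loop_fill <- function(span, len) {
  if (len == 0L) return(integer())
  w <- length(span)
  left <- ceiling(len / 2)
  right <- len - left
  c(span[seq_len(left)], if (right > 0L) span[w - right + seq_len(right)])
}

# Positions occupied in every structure, given the minimum loop lengths.
always_occupied <- function(layout, loop_lengths) {
  occ <- unlist(layout$spans[c("FR1", "FR2", "FR3", "FR4")],
                use.names = FALSE)
  for (nm in c("H1", "H2", "H3")) {
    minlen <- min(as.integer(names(loop_lengths[[nm]])))
    occ <- c(occ, loop_fill(layout$spans[[nm]], minlen))
  }
  sort(occ)
}

#' Generate a synthetic immunoglobulin-like family on disk
#'
#' Emits one PDB file and one numbering CSV per structure, a dataset
#' manifest, and a ground-truth JSON. Coordinates are the scaffold
#' trace plus isotropic Gaussian noise with per-region sigma; loop
#' lengths are drawn per spec with unoccupied central columns absent
#' from both file and numbering; sequences are drawn per column (modal
#' residue with the target probability, remainder uniform over the
#' other 19 letters). For bound families an antigen pseudo-chain is
#' placed so that exactly \code{round(propensity * n)} structures
#' contact each designated paratope position at 4.0--4.8 Angstrom,
#' while every non-contact residue stays > 5.5 Angstrom from all
#' antigen atoms (verified at generation time).
#'
#' @param spec A \code{family_spec}.
#' @param dir Output directory (created if needed).
#' @return List with \code{dir}, \code{manifest} (path),
#'   \code{ground_truth} (list, also written to
#'   \code{ground_truth.json}) and \code{spec}.
#' @export
generate_family <- function(spec, dir) {
  stopifnot(inherits(spec, "family_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- spec$layout
  scaffold <- make_scaffold(layout)
  n <- spec$n

  if (length(spec$paratope_positions) > 0L) {
    ao <- always_occupied(layout, spec$loop_lengths)
    missing_par <- setdiff(spec$paratope_positions, ao)
    if (length(missing_par) > 0L) {
      stop("designated paratope position(s) not occupied in every ",
           "structure: ", paste(missing_par, collapse = ","))
    }
  }

  col_sigma <- ifelse(layout$labels %in% c("H1", "H2", "H3"),
                      spec$loop_sigma[layout$labels], spec$fr_sigma)
  col_cons <- ifelse(layout$labels %in% c("H1", "H2", "H3"),
                     spec$loop_conservation[layout$labels],
                     spec$fr_conservation)

  res <- with_local_seed(spec$seed, {
    modal <- sample(AA20, layout$length, replace = TRUE)
    # designed contacts: exactly round(propensity * n) structures per
    # designated position
    contact_mat <- matrix(FALSE, n, layout$length)
    for (k in seq_along(spec$paratope_positions)) {
      cnt <- round(spec$paratope_propensity[k] * n)
      if (cnt > 0L) {
        contact_mat[sample.int(n, cnt), spec$paratope_positions[k]] <- TRUE
      }
    }
    species <- sample(spec$species, n, replace = TRUE,
                      prob = spec$species_prob)
    structures <- vector("list", n)
    for (i in seq_len(n)) {
      lens <- vapply(c("H1", "H2", "H3"), function(nm) {
        ll <- spec$loop_lengths[[nm]]
        as.integer(sample(names(ll), 1L, prob = ll))
      }, integer(1))
      occ <- unlist(layout$spans[c("FR1", "FR2", "FR3", "FR4")],
                    use.names = FALSE)
      for (nm in c("H1", "H2", "H3")) {
        occ <- c(occ, loop_fill(layout$spans[[nm]], lens[[nm]]))
      }
      occ <- sort(occ)
      aa <- vapply(occ, function(p) {
        if (stats::runif(1) < col_cons[p]) modal[p] else
          sample(setdiff(AA20, modal[p]), 1L)
      }, character(1))
      xyz <- scaffold[occ, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(occ), 0, rep(col_sigma[occ], 3)),
               ncol = 3)
      miss <- stats::runif(length(occ)) < spec$miss_frac
      structures[[i]] <- list(occ = occ, aa = aa, xyz = xyz, miss = miss,
                              lens = lens,
                              contacts = which(contact_mat[i, occ]))
    }
    list(modal = modal, contact_mat = contact_mat, species = species,
         structures = structures)
  })

  manifest <- data.frame(file = character(), binder_chain = character(),
                         antigen_chains = character(), species = character(),
                         state = character(), stringsAsFactors = FALSE)
  contact_counts <- integer(n)
  loop_length_mat <- matrix(NA_integer_, n, 3,
                            dimnames = list(NULL, c("H1", "H2", "H3")))
  numbering_dir <- file.path(dir, "numbering")
  dir.create(numbering_dir, showWarnings = FALSE)

  for (i in seq_len(n)) {
    st <- res$structures[[i]]
    sid <- sprintf("%s_%03d", spec$name, i)
    emitted <- with_local_seed(spec$seed + 7919L * i, {
      emit_structure(st, sid, spec, layout, dir, numbering_dir)
    })
    contact_counts[i] <- length(st$contacts)
    loop_length_mat[i, ] <- st$lens
    manifest <- rbind(manifest, data.frame(
      file = basename(emitted$pdb), binder_chain = "A",
      antigen_chains = if (spec$state == "bound") "B" else "",
      species = res$species[i], state = spec$state,
      stringsAsFactors = FALSE))
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ground_truth <- list(
    name = spec$name, n = n, state = spec$state,
    sigma = c(list(FR = spec$fr_sigma), as.list(spec$loop_sigma)),
    conservation = c(list(FR = spec$fr_conservation),
                     as.list(spec$loop_conservation)),
    modal_residues = res$modal,
    region_labels = layout$labels,
    paratope_positions = spec$paratope_positions,
    designed_contacts_per_position =
      as.integer(round(spec$paratope_propensity * n)),
    contact_counts = contact_counts,
    loop_lengths = as.data.frame(loop_length_mat),
    species = res$species,
    seed = spec$seed
  )
  jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10)
  list(dir = dir, manifest = manifest_path, ground_truth = ground_truth,
       spec = spec)
}

# Emit one structure: PDB (binder chain A [+ antigen chain B]) and
# numbering CSV. Contact geometry: contact residues get a side-chain
# pseudo-atom (CB) 4.5 A radially outward of the C-alpha and an antigen
# atom 4.0-4.8 A beyond it; placement directions are searched so every
# non-contact residue stays > 5.5 A from all antigen atoms.
emit_structure <- function(st, sid, spec, layout, dir, numbering_dir) {
  occ <- st$occ
  n_res <- length(occ)
  radial <- function(v) {
    u <- c(v[1], v[2], 0)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) c(1, 0, 0) else u / nu
  }
  is_contact <- seq_len(n_res) %in% st$contacts
  atoms <- list()
  for (r in seq_len(n_res)) {
    ca <- st$xyz[r, ]
    if (!st$miss[r]) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        res_index = r, elety = "CA", elesy = "C",
        resno = occ[r], x = ca[1], y = ca[2], z = ca[3])
    } else if (!is_contact[r]) {
      # residue with a missing C-alpha keeps one side-chain pseudo-atom
      cb <- ca + 1.5 * radial(ca)
      atoms[[length(atoms) + 1L]] <- data.frame(
        res_index = r, elety = "CB", elesy = "C",
        resno = occ[r], x = cb[1], y = cb[2], z = cb[3])
    }
  }
  atoms <- do.call(rbind, atoms)

  antigen <- NULL
  if (spec$state == "bound") {
    non_contact_xyz <-
      as.matrix(atoms[!(atoms$res_index %in% st$contacts),
                      c("x", "y", "z")])
    ag <- matrix(NA_real_, 0, 3)
    # each contact residue gets a side-chain pseudo-atom 3 A from its
    # C-alpha with its antigen atom a further 4.0-4.8 A along the same
    # direction; the direction is searched so the antigen atom clears
    # every non-contact residue by > 5.5 A
    for (r in st$contacts) {
      ca <- st$xyz[r, ]
      u <- radial(ca)
      d <- stats::runif(1, 4.0, 4.8)
      best_w <- NULL
      best_clear <- -Inf
      for (try in seq_len(400L)) {
        w <- if (try == 1L) u else {
          v <- stats::rnorm(3)
          v / sqrt(sum(v^2))
        }
        pos <- ca + (3 + d) * w
        clear <- if (nrow(non_contact_xyz) == 0L) Inf else
          min(sqrt(rowSums(sweep(non_contact_xyz, 2, pos)^2)))
        if (clear > best_clear) {
          best_w <- w
          best_clear <- clear
        }
        if (clear > 6.5) break  # comfortably clear; stop early
      }
      if (best_clear <= 5.5) {
        stop("could not place antigen atom for residue ", r, " of ", sid)
      }
      cb <- ca + 3 * best_w
      atoms <- rbind(atoms, data.frame(
        res_index = r, elety = "CB", elesy = "C",
        resno = occ[r], x = cb[1], y = cb[2], z = cb[3]))
      ag <- rbind(ag, ca + (3 + d) * best_w)
    }
    atoms <- atoms[order(atoms$res_index), , drop = FALSE]
    if (nrow(ag) == 0L) {
      # bound record must have antigen atoms even with no designed contacts
      ag <- matrix(c(0, 0, min(st$xyz[, 3]) - 30), 1, 3)
    }
    antigen <- data.frame(
      elety = "CA", elesy = "C", resid = "ALA", chain = "B",
      resno = seq_len(nrow(ag)),
      x = ag[, 1], y = ag[, 2], z = ag[, 3])

    # generation-time verification: detected contacts == designed
    bxyz <- as.matrix(atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(bxyz^2), rowSums(ag^2), "+") -
      2 * tcrossprod(bxyz, ag)
    amin <- sqrt(pmax(apply(d2, 1, min), 0))
    rmin <- tapply(amin, atoms$res_index, min)
    det_contact <- as.integer(names(rmin))[rmin < 5.0]
    if (!setequal(det_contact, st$contacts) ||
        any(rmin[!(as.integer(names(rmin)) %in% st$contacts)] <= 5.5)) {
      stop("contact geometry verification failed for ", sid)
    }
  }

  dom <- structure(list(sequence = paste(st$aa, collapse = ""),
                        aa = st$aa, atoms = atoms,
                        has_ca = !st$miss, resno = occ,
                        insert = rep("", n_res)),
                   class = "domain_structure")
  pdb_path <- file.path(dir, paste0(sid, ".pdb"))
  write_domain_pdb(dom, pdb_path, chain = "A", extra = antigen)

  num_path <- file.path(numbering_dir, paste0(sid, "_A.csv"))
  writeLines(c(sprintf("# scheme_length: %d", layout$length),
               "scheme_position,insertion_code,residue",
               sprintf("%d,,%s", occ, st$aa)),
             num_path)
  list(pdb = pdb_path, numbering = num_path)
}

#' Numbering tables of a generated family, in manifest order
#'
#' @param family Result of [generate_family()].
#' @return List of \code{numbered_sequence} objects.
#' @export
family_numbering <- function(family) {
  man <- utils::read.delim(family$manifest, stringsAsFactors = FALSE,
                           colClasses = "character")
  paths <- file.path(family$dir, "numbering",
                     paste0(sub("\\.pdb$", "", man$file), "_",
                            man$binder_chain, ".csv"))
  lapply(paths, read_numbering_csv)
}

#' Paired synthetic families emulating a single-domain vs conventional
#' antibody contrast
#'
#' The \code{nb_like} preset plants the hallmark single-domain (VHH)
#' family characteristics relative to \code{ab_like}: a more conserved
#' and structurally tighter framework, a longer and structurally much
#' noisier H3 loop, more sequence-diverse H3, and a broader paratope
#' (50 designated positions against 35). Noise sigmas are chosen so
#' that the expected pairwise RMSD (about sqrt(6) sigma for isotropic
#' per-atom noise) matches each region's target structural
#' variability, and per-column conservation targets are chosen to give
#' the target per-loop mean Hamming distances.
#'
#' @param dir Output directory; the two families go to
#'   \code{<dir>/nb_like} and \code{<dir>/ab_like}.
#' @param n Structures per family (default 90).
#' @param seed Integer seed; the second family derives its seed from
#'   \code{seed + 1}.
#' @return List with elements \code{nb} and \code{ab}, each a
#'   [generate_family()] result.
#' @export
make_paper_like_pair <- function(dir, n = 90L, seed = 1L) {
  layout <- scheme_layout()
  sp <- layout$spans
  # always-occupied loop flanks at the minimum loop lengths below
  nb_paratope <- c(1:3,                      # N-terminal patch
                   sp$H1[c(1:5, 11:14)],     # H1 flanks (min length 9)
                   sp$FR2[1:8],
                   sp$H2[c(1:5, 11:14)],     # H2 flanks
                   sp$FR3[1:5], sp$FR3[33:38],
                   sp$H3[c(1:4, 28:31)],     # H3 flanks (min length 8)
                   sp$FR4[1:2])
  ab_paratope <- c(sp$H1[c(1:5, 11:14)],
                   sp$FR2[1:3],
                   sp$H2[c(1:5, 11:14)],
                   sp$FR3[1:3], sp$FR3[34:38],
                   sp$H3[c(1:3, 29:31)])     # H3 flanks (min length 6)
  nb_prop <- seq(0.15, 0.60, length.out = length(nb_paratope))
  nb_prop <- nb_prop * (18.76 / sum(nb_prop))
  ab_prop <- seq(0.20, 0.715, length.out = length(ab_paratope))
  ab_prop <- ab_prop * (16.01 / sum(ab_prop))

  nb_spec <- family_spec(
    name = "nb_like", n = n, state = "bound",
    fr_sigma = 0.41,
    loop_sigma = c(H1 = 1.37, H2 = 0.76, H3 = 2.62),
    loop_lengths = list(
      H1 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
      H2 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
      H3 = discrete_normal_lengths(15.19, 4.23, 8, 29)),
    fr_conservation = 0.85,
    loop_conservation = c(H1 = 0.565, H2 = 0.54, H3 = 0.29),
    paratope_positions = nb_paratope,
    paratope_propensity = nb_prop,
    species = c("llama", "camel", "alpaca"),
    species_prob = c(60, 24, 6),
    seed = seed, layout = layout)
  ab_spec <- family_spec(
    name = "ab_like", n = n, state = "bound",
    fr_sigma = 0.46,
    loop_sigma = c(H1 = 0.65, H2 = 0.73, H3 = 1.44),
    loop_lengths = list(
      H1 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
      H2 = c("9" = 0.1, "10" = 0.8, "11" = 0.1),
      H3 = discrete_normal_lengths(12.09, 3.81, 6, 29)),
    fr_conservation = 0.60,
    loop_conservation = c(H1 = 0.565, H2 = 0.475, H3 = 0.39),
    paratope_positions = ab_paratope,
    paratope_propensity = ab_prop,
    species = c("human", "mouse"),
    species_prob = c(1, 1),
    seed = seed + 1L, layout = layout)

  list(nb = generate_family(nb_spec, file.path(dir, "nb_like")),
       ab = generate_family(ab_spec, file.path(dir, "ab_like")))
}
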