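# Shared fixture builders; everything is constructed in code.

# Fixed-width PDB ATOM line
pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, alt = " ", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(name, 1, 1)
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, elesy)
}

# Three-residue chain A (GLU-VAL-GLY; VAL lacks its C-alpha) plus a
# two-residue antigen chain B; written as PDB or the equivalent mmCIF.
mini_structure_atoms <- function() {
  list(
    list(name = "N",  resid = "GLU", chain = "A", resno = 1,
         xyz = c(0.000, 0.000, 0.000)),
    list(name = "CA", resid = "GLU", chain = "A", resno = 1,
         xyz = c(1.458, 0.000, 0.000)),
    list(name = "CB", resid = "GLU", chain = "A", resno = 1,
         xyz = c(2.000, 1.400, 0.000)),
    list(name = "N",  resid = "VAL", chain = "A", resno = 2,
         xyz = c(2.200, -1.000, 0.500)),
    list(name = "CB", resid = "VAL", chain = "A", resno = 2,
         xyz = c(3.600, -1.200, 0.800)),
    list(name = "CA", resid = "GLY", chain = "A", resno = 3,
         xyz = c(6.000, -2.000, 1.500)),
    list(name = "CA", resid = "ALA", chain = "B", resno = 1,
         xyz = c(15.000, 0.000, 0.000)),
    list(name = "CB", resid = "ALA", chain = "B", resno = 1,
         xyz = c(16.000, 0.500, 0.000)),
    list(name = "CA", resid = "SER", chain = "B", resno = 2,
         xyz = c(18.000, 1.000, 0.500))
  )
}

write_mini_pdb <- function(path, atoms = mini_structure_atoms()) {
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    pdb_atom_line(i, a$name, a$resid, a$chain, a$resno, a$xyz)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_mini_cif <- function(path, atoms = mini_structure_atoms()) {
  head <- c(
    "data_mini", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            i, substr(a$name, 1, 1), a$name, a$resid, a$chain, a$resno,
            a$xyz[1], a$xyz[2], a$xyz[3], a$resno, a$resid, a$chain,
            a$name)
  }, character(1))
  writeLines(c(head, rows, "#"), path)
  path
}

# Manifest + structure files for a tiny dataset in its own directory
write_mini_dataset <- function(dir, rows, atoms = mini_structure_atoms()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in unique(rows$file)) {
    write_mini_pdb(file.path(dir, f), atoms)
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(rows, man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man
}

# Numbering CSV for a toy record
write_numbering <- function(path, positions, residues,
                            scheme_length = NULL) {
  lines <- character()
  if (!is.null(scheme_length)) {
    lines <- sprintf("# scheme_length: %d", scheme_length)
  }
  writeLines(c(lines, "scheme_position,insertion_code,residue",
               sprintf("%d,,%s", positions, residues)), path)
  path
}

# Random proper rotation matrix (via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent numerical oracle for the optimal rigid-body RMSD:
# minimize over Euler angles and translation with multi-start
# quasi-Newton search.
rmsd_numeric_oracle <- function(X, Y, n_starts = 24) {
  rot_from_angles <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rot_from_angles(par[1:3])
    Yt <- Y %*% t(R) + matrix(par[4:6], nrow(Y), 3, byrow = TRUE)
    sqrt(mean(rowSums((X - Yt)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- c(stats::runif(3, -pi, pi), colMeans(X) - colMeans(Y))
    fit <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Toy complex with explicit atom coordinates; binder residues each get
# the given atom coordinate rows, the antigen is a plain atom matrix.
make_toy_complex <- function(binder_res_xyz, antigen_xyz,
                             state = "bound") {
  atoms <- do.call(rbind, lapply(seq_along(binder_res_xyz), function(i) {
    m <- binder_res_xyz[[i]]
    if (is.null(dim(m))) m <- matrix(m, 1)
    data.frame(res_index = i,
               elety = paste0("C", seq_len(nrow(m))),
               elesy = "C", resno = i,
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
  atoms$elety[!duplicated(atoms$res_index)] <- "CA"
  n <- length(binder_res_xyz)
  binder <- structure(list(sequence = strrep("A", n),
                           aa = rep("A", n), atoms = atoms,
                           has_ca = rep(TRUE, n), resno = seq_len(n),
                           insert = rep("", n)),
                      class = "domain_structure")
  antigen <- if (is.null(antigen_xyz)) {
    data.frame(x = numeric(), y = numeric(), z = numeric())
  } else {
    data.frame(elety = "CA", elesy = "C",
               resno = seq_len(nrow(antigen_xyz)),
               x = antigen_xyz[, 1], y = antigen_xyz[, 2],
               z = antigen_xyz[, 3], stringsAsFactors = FALSE)
  }
  structure(list(binder = binder, antigen = antigen, species = "toy",
                 state = state, id = "toy"),
            class = "complex_record")
}

# Cached small paper-like pair shared across test files in one run
toy_pair_cache <- new.env(parent = emptyenv())
get_small_pair <- function(n = 20, seed = 101) {
  key <- paste0("pair_", n, "_", seed)
  if (!exists(key, envir = toy_pair_cache)) {
    assign(key, make_paper_like_pair(tempfile("pair"), n = n, seed = seed),
           envir = toy_pair_cache)
  }
  get(key, envir = toy_pair_cache)
}
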