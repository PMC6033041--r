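test_that("PDB and mmCIF fixtures parse to the same chain map", {
  pdb <- write_mini_pdb(tempfile(fileext = ".pdb"))
  cif <- write_mini_cif(tempfile(fileext = ".cif"))
  cp <- parse_structure(pdb)
  cc <- parse_structure(cif)

  expect_named(cp, c("A", "B"))
  expect_equal(cp$A$sequence, "EVG")
  expect_equal(nchar(cp$A$sequence), 3L)
  # VAL at index 2 lacks a C-alpha but keeps its heavy atoms
  expect_equal(cp$A$has_ca, c(TRUE, FALSE, TRUE))
  expect_equal(sum(cp$A$atoms$res_index == 2L), 2L)

  expect_equal(names(cc), names(cp))
  for (ch in names(cp)) {
    expect_equal(cc[[ch]]$sequence, cp[[ch]]$sequence)
    expect_equal(cc[[ch]]$has_ca, cp[[ch]]$has_ca)
    expect_equal(cc[[ch]]$atoms[, c("x", "y", "z")],
                 cp[[ch]]$atoms[, c("x", "y", "z")],
                 tolerance = 1e-6)
  }
})

test_that("hydrogens are dropped and altlocs resolve by occupancy", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "H", "GLY", "A", 1, c(0.5, 0, 0), elesy = "H"),
    pdb_atom_line(3, "CA", "SER", "A", 2, c(3.8, 0, 0), occ = 0.3,
                  alt = "A"),
    pdb_atom_line(4, "CA", "SER", "A", 2, c(4.8, 0, 0), occ = 0.7,
                  alt = "B"),
    pdb_atom_line(5, "CA", "ALA", "A", 3, c(7.6, 0, 0), occ = 0.5,
                  alt = "A"),
    pdb_atom_line(6, "CA", "ALA", "A", 3, c(8.6, 0, 0), occ = 0.5,
                  alt = "B"),
    "END"), path)
  ch <- parse_structure(path)$A
  expect_false(any(ch$atoms$elesy == "H"))
  # highest occupancy wins
  expect_equal(ch$atoms$x[ch$atoms$res_index == 2L], 4.8)
  # occupancy tie goes to conformer A
  expect_equal(ch$atoms$x[ch$atoms$res_index == 3L], 7.6)
  # nonstandard residues map to X
  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "SEP", "A", 1, c(0, 0, 0)),
               pdb_atom_line(2, "CA", "GLY", "A", 2, c(3.8, 0, 0)),
               "END"), path2)
  expect_equal(parse_structure(path2)$A$sequence, "XG")
})

test_that("unparseable and empty-polymer files raise errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("HETATM    1  O   HOH B   1      20.000  20.000  20.000  1.00  0.00           O",
             bad)
  expect_error(parse_structure(bad), "polymer")
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("build_complex collects antigen atoms from the listed chains only", {
  pdb <- write_mini_pdb(tempfile(fileext = ".pdb"))
  chains <- parse_structure(pdb)
  row <- list(file = pdb, binder_chain = "A", antigen_chains = "B",
              species = "llama", state = "bound")
  rec <- build_complex(row, chains)
  expect_s3_class(rec, "complex_record")
  expect_equal(rec$state, "bound")
  expect_equal(nrow(rec$antigen), 3L)  # all chain-B heavy atoms
  expect_true(all(rec$antigen$chain == "B"))

  apo <- build_complex(list(file = pdb, binder_chain = "A",
                            antigen_chains = "", species = "llama",
                            state = "apo"), chains)
  expect_equal(apo$state, "apo")
  expect_equal(nrow(apo$antigen), 0L)

  expect_error(build_complex(list(file = pdb, binder_chain = "A",
                                  antigen_chains = "Z", species = "x",
                                  state = "bound"), chains),
               "antigen chain")
  expect_error(build_complex(list(file = pdb, binder_chain = "Q",
                                  antigen_chains = "B", species = "x",
                                  state = "bound"), chains),
               "binder chain")
})

test_that("multi-chain antigens sum their heavy atoms", {
  atoms <- c(mini_structure_atoms(),
             list(list(name = "CA", resid = "GLY", chain = "C", resno = 1,
                       xyz = c(25, 0, 0)),
                  list(name = "CB", resid = "GLY", chain = "C", resno = 1,
                       xyz = c(26, 0, 0))))
  pdb <- write_mini_pdb(tempfile(fileext = ".pdb"), atoms)
  chains <- parse_structure(pdb)
  rec <- build_complex(list(file = pdb, binder_chain = "A",
                            antigen_chains = "B,C", species = "x",
                            state = "bound"), chains)
  expect_equal(nrow(rec$antigen), 3L + 2L)
})

test_that("load_dataset deduplicates identical binder sequences and aggregates errors", {
  dir <- tempfile("ds")
  rows <- data.frame(
    file = c("s1.pdb", "s2.pdb", "s3.pdb"),
    binder_chain = "A", antigen_chains = "B",
    species = "llama", state = "bound", stringsAsFactors = FALSE)
  man <- write_mini_dataset(dir, rows)
  # s3 gets a different sequence (mutate GLU -> ALA)
  atoms <- mini_structure_atoms()
  atoms[[1]]$resid <- atoms[[2]]$resid <- atoms[[3]]$resid <- "ALA"
  write_mini_pdb(file.path(dir, "s3.pdb"), atoms)

  expect_message(recs <- load_dataset(man, dedup = TRUE), "duplicate")
  expect_length(recs, 2L)
  expect_length(load_dataset(man, dedup = FALSE), 3L)

  rows_bad <- rbind(rows, data.frame(file = "missing.pdb",
                                     binder_chain = "A",
                                     antigen_chains = "B",
                                     species = "x", state = "bound"))
  man2 <- file.path(dir, "manifest2.tsv")
  utils::write.table(rows_bad, man2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_dataset(man2), "missing.pdb")

  rows_dup <- rbind(rows, rows[1, ])
  man3 <- file.path(dir, "manifest3.tsv")
  utils::write.table(rows_dup, man3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_dataset(man3), "duplicate \\(file, binder_chain\\)")
})

test_that("record content does not depend on manifest row order", {
  dir <- tempfile("ds")
  rows <- data.frame(
    file = c("s1.pdb", "s2.pdb"), binder_chain = "A",
    antigen_chains = "B", species = c("llama", "camel"),
    state = "bound", stringsAsFactors = FALSE)
  man <- write_mini_dataset(dir, rows)
  fwd <- load_dataset(man, dedup = FALSE)
  man_rev <- file.path(dir, "rev.tsv")
  utils::write.table(rows[2:1, ], man_rev, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rev <- load_dataset(man_rev, dedup = FALSE)
  expect_equal(fwd[[1]], rev[[2]])
  expect_equal(fwd[[2]], rev[[1]])
})

test_that("write/parse round-trip preserves sequence and coordinates", {
  pdb <- write_mini_pdb(tempfile(fileext = ".pdb"))
  dom <- parse_structure(pdb)$A
  out <- tempfile(fileext = ".pdb")
  write_domain_pdb(dom, out, chain = "A")
  dom2 <- parse_structure(out)$A
  expect_equal(dom2$sequence, dom$sequence)
  expect_equal(dom2$has_ca, dom$has_ca)
  expect_equal(as.matrix(dom2$atoms[, c("x", "y", "z")]),
               as.matrix(dom$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
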