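# Descriptor registry, native fingerprints, PaDEL-format import.

test_that("the registry fixes the nine family widths and kinds", {
  reg <- fp_registry()
  widths <- setNames(reg$width, reg$name)
  expect_equal(widths[c("AP2D", "AP2DC", "KR", "KRC", "MACCS",
                        "Pubchem", "FP4", "FP4C", "RDK5")],
               c(AP2D = 780L, AP2DC = 780L, KR = 4860L, KRC = 4860L,
                 MACCS = 166L, Pubchem = 881L, FP4 = 307L, FP4C = 307L,
                 RDK5 = 2048L))
  expect_setequal(reg$name[reg$value_kind == "count"],
                  c("AP2DC", "KRC", "FP4C"))
  expect_equal(registry_entry("MACCS")$width, 166L)
  expect_error(registry_entry("ECFP4"), "registry")
})

test_that("native MACCS keys match an independent reference implementation", {
  data <- tibble::tibble(id = c("benzene", "ethanol"),
                         smiles_canonical = c("c1ccccc1", "CCO"))
  block <- compute_fp(data, "MACCS")
  expect_equal(dim(block$matrix), c(2L, 166L))
  # independent oracle: RDKit's MACCS implementation on the same SMILES
  script <- paste(
    "from rdkit import Chem",
    "from rdkit.Chem import MACCSkeys",
    "for s in ['c1ccccc1','CCO']:",
    "    fp = MACCSkeys.GenMACCSKeys(Chem.MolFromSmiles(s))",
    "    print(','.join(str(b) for b in fp.GetOnBits()))",
    sep = "\n")
  ref <- system2("python", "-", input = script, stdout = TRUE)
  ref_bits <- lapply(strsplit(ref, ","), as.integer)
  expect_equal(which(block$matrix[1, ] == 1), ref_bits[[1]],
               ignore_attr = TRUE)
  expect_equal(which(block$matrix[2, ] == 1), ref_bits[[2]],
               ignore_attr = TRUE)
})

test_that("the hashed path fingerprint is binary, wide and deterministic", {
  cur <- tiny_curated()[1:8, ]
  b1 <- compute_fp(cur, "RDK5")
  expect_equal(ncol(b1$matrix), 2048L)
  expect_true(all(b1$matrix %in% c(0L, 1L)))
  expect_gt(sum(b1$matrix), 0)
  # identical SMILES give identical vectors, independent of row order
  b2 <- compute_fp(cur[rev(seq_len(8)), ], "RDK5")
  expect_equal(unname(b1$matrix[1, ]), unname(b2$matrix[8, ]))
  expect_equal(unname(b1$matrix[5, ]), unname(b2$matrix[4, ]))
  # empty input gives a 0 x width block
  empty <- compute_fp(cur[0, ], "MACCS")
  expect_equal(dim(empty$matrix), c(0L, 166L))
})

test_that("a molecule and its substructure share path bits", {
  # every path of toluene's benzene ring occurs in benzene as well
  d <- tibble::tibble(id = c("benzene", "toluene"),
                      smiles_canonical = c("c1ccccc1", "Cc1ccccc1"))
  b <- compute_fp(d, "RDK5")
  benzene_bits <- which(b$matrix[1, ] == 1)
  toluene_bits <- which(b$matrix[2, ] == 1)
  expect_true(all(benzene_bits %in% toluene_bits))
})

test_that("PaDEL-format import validates width, values and alignment", {
  cur <- tiny_curated()[1:10, ]
  block <- gen_fp_block(cur, "FP4", signal_frac = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_block(block, path)
  back <- import_fp_block(path, "FP4", cur)
  expect_identical(back$matrix, block$matrix)            # bit-exact round trip
  # rows are reordered to match the compound table
  shuffled <- import_fp_block(path, "FP4", cur[c(3, 1, 2, 4:10), ])
  expect_equal(unname(shuffled$matrix[1, ]), unname(block$matrix[3, ]))

  expect_error(import_fp_block(path, "Pubchem", cur), "schema")
  expect_error(import_fp_block(path, "FP4",
                               tibble::tibble(id = "nope")), "alignment")
  bad <- block; bad$matrix[1, 1] <- 2L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fp_block(bad, path2)
  expect_error(import_fp_block(path2, "FP4", cur), "value error")
})

test_that("count families import as non-negative integers", {
  cur <- tiny_curated()[1:6, ]
  blk <- gen_fp_block(cur, "FP4C", signal_frac = 0.02, seed = 9)
  expect_true(all(blk$matrix >= 0))
  expect_true(all(blk$matrix == floor(blk$matrix)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_block(blk, path)
  expect_identical(import_fp_block(path, "FP4C", cur)$matrix, blk$matrix)
})

test_that("available descriptors are the natives plus configured imports", {
  expect_setequal(available_descriptors(), c("MACCS", "RDK5"))
  expect_setequal(
    available_descriptors(list(Pubchem = "p.csv", KR = "k.csv")),
    c("MACCS", "RDK5", "Pubchem", "KR"))
  all9 <- available_descriptors(as.list(setNames(
    paste0(c("AP2D", "AP2DC", "KR", "KRC", "Pubchem", "FP4", "FP4C"), ".csv"),
    c("AP2D", "AP2DC", "KR", "KRC", "Pubchem", "FP4", "FP4C"))))
  expect_setequal(all9, fp_registry()$name)
  expect_error(available_descriptors(list(ECFP4 = "x.csv")), "registry")
})
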