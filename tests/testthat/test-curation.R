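# Curation: table reading, standardization, deduplication, labeling, splits.

test_that("compound tables are read with unit conversion and dialect mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50,unit",
               "a,CCO,0.5,uM",
               "b,c1ccccc1,2000,nM",
               "c,CCN,0.001,mM"), path)
  tab <- read_compound_table(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$ic50_nM, c(500, 2000, 1000))

  chembl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Molecule ChEMBL ID,Smiles,Standard Value,Standard Units",
               "CHEMBL1,CCO,500,nM",
               "CHEMBL2,CCC,1.5,uM"), chembl)
  tab2 <- read_compound_table(chembl, dialect = "chembl_export")
  expect_equal(tab2$id, c("CHEMBL1", "CHEMBL2"))
  expect_equal(tab2$ic50_nM, c(500, 1500))

  nosmiles <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ic50_nM", "a,100"), nosmiles)
  expect_error(read_compound_table(nosmiles), "SMILES")

  badunit <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50,unit", "a,CCO,1,mol/kg", "b,CCC,5,nM"), badunit)
  expect_warning(tab3 <- read_compound_table(badunit), "unconvertible")
  expect_equal(tab3$id, "b")
  expect_error(read_compound_table(badunit, on_bad_units = "error"))
})

test_that("standardization desalts, canonicalizes and is idempotent", {
  expect_equal(standardize_structure("CCO.Cl"), "CCO")
  benzene <- standardize_structure("C1=CC=CC=C1")
  expect_equal(standardize_structure(benzene), benzene)  # idempotent
  expect_equal(standardize_structure(standardize_structure("CCO.Cl")), "CCO")
  # larger organic fragment wins regardless of component order
  expect_equal(standardize_structure("Cl.CC(=O)O"),
               standardize_structure("CC(=O)O"))
  expect_error(standardize_structure("C1CC"), "unparseable")
  expect_error(standardize_structure("[Na+].[Cl-]"), "organic")
})

test_that("standardization is idempotent across a generated dataset", {
  cur <- tiny_curated()
  twice <- vapply(cur$smiles_canonical, standardize_structure, character(1))
  expect_equal(unname(twice), cur$smiles_canonical)
})

test_that("deduplication keeps the median IC50 and first-occurrence order", {
  base <- tibble::tibble(
    id = c("a", "b", "c", "d", "e"),
    smiles_raw = c("CCO", "OCC", "CCC", "C1=CC=CC=C1", "c1ccccc1"),
    ic50_nM = c(100, 300, 50, 10, 100000)) |>
    standardize_compounds()
  out <- deduplicate_compounds(base)
  expect_equal(nrow(out), 3)
  expect_equal(out$id, c("a", "c", "d"))                # first occurrence
  expect_equal(out$ic50_nM[out$id == "a"], 200)         # median of two
  expect_equal(out$ic50_nM[out$id == "d"], 50005)       # median of {10, 1e5}

  trip <- tibble::tibble(id = c("x", "y", "z"),
                         smiles_raw = rep("CCO", 3),
                         ic50_nM = c(10, 1000, 100000)) |>
    standardize_compounds()
  expect_equal(deduplicate_compounds(trip)$ic50_nM, 1000)  # median of three

  uniq <- tibble::tibble(id = c("u", "v"), smiles_raw = c("CCO", "CCC"),
                         ic50_nM = c(1, 2)) |> standardize_compounds()
  expect_equal(deduplicate_compounds(uniq)$id, uniq$id)   # identity case
  expect_lte(nrow(deduplicate_compounds(base)), nrow(base))
})

test_that("labels partition the IC50 axis into three intervals", {
  thr <- label_thresholds()
  expect_equal(as.character(assign_label(c(500, 20000, 5000, NA), thr)),
               c("active", "inactive", "intermediate", "unlabeled"))
  # boundary values belong to the outer classes
  expect_equal(as.character(assign_label(c(1000, 10000), thr)),
               c("active", "inactive"))
  expect_error(assign_label(-1, thr))
  expect_error(label_thresholds(10000, 1000))
  # every positive IC50 receives exactly one label
  grid <- c(10^seq(-2, 8, length.out = 200))
  labs <- assign_label(grid, thr)
  expect_false(anyNA(labs))
  expect_setequal(as.character(unique(labs)),
                  c("active", "intermediate", "inactive"))
})

test_that("stratified split draws per-class floor counts deterministically", {
  cur <- tiny_curated(30, 20)
  sp <- stratified_split(cur, 0.8, seed = 42)
  tr <- sp[sp$split == "train", ]; te <- sp[sp$split == "test", ]
  expect_equal(sum(tr$label == "active"), floor(0.8 * sum(cur$label == "active")))
  expect_equal(sum(tr$label == "inactive"), floor(0.8 * sum(cur$label == "inactive")))
  expect_setequal(c(tr$id, te$id), cur$id)               # union = all labeled
  expect_length(intersect(tr$id, te$id), 0)              # disjoint
  sp2 <- stratified_split(cur, 0.8, seed = 42)
  expect_identical(sp$split, sp2$split)                  # seeded determinism
  sp3 <- stratified_split(cur, 0.8, seed = 43)
  expect_false(identical(sp$split, sp3$split))

  all_train <- stratified_split(cur, 1.0, seed = 1)
  expect_equal(sum(all_train$split == "test"), 0)

  one_class <- cur[cur$label == "active", ]
  expect_error(stratified_split(one_class, 0.8, 1), "stratify")
})

test_that("curated datasets round-trip through CSV", {
  cur <- stratified_split(tiny_curated(), 0.8, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curated_csv(cur[, c("id", "smiles_raw", "smiles_canonical",
                            "ic50_nM", "label", "split")], path)
  back <- read_curated_csv(path)
  expect_equal(back$id, cur$id)
  expect_equal(back$ic50_nM, cur$ic50_nM)
  expect_equal(as.character(back$label), as.character(cur$label))
  expect_equal(as.character(back$split), as.character(cur$split))
})
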