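test_that("a container round-trips through .h5mu with full fidelity", {
  for (seed in c(1, 7, 13)) {
    mc <- random_container(seed)
    f <- tmp_h5mu()
    write_h5mu(mc, f)
    expect_container_equal(mc, read_h5mu(f))
  }
})

test_that("the file layout matches the dialect contract", {
  mc <- toy_container()
  f <- tmp_h5mu()
  write_h5mu(mc, f)
  at <- rhdf5::h5readAttributes(f, "/")
  expect_identical(as.vector(at[["encoding-type"]]), "MuData")
  expect_identical(as.vector(at[["encoding-version"]]), "0.1.0")
  expect_identical(as.vector(rhdf5::h5readAttributes(f, "mod")[["mod-order"]]),
                   c("rna", "atac"))
  ls <- rhdf5::h5ls(f)
  expect_true(all(c("obs", "var", "obsmap", "varmap", "mod") %in% ls$name[ls$group == "/"]))
  # sparse modality stored as CSR group with shape attribute
  xat <- rhdf5::h5readAttributes(f, "mod/atac/X")
  expect_identical(as.vector(xat[["encoding-type"]]), "csr_matrix")
  expect_identical(as.integer(xat[["shape"]]), c(3L, 2L))
  expect_true(all(c("data", "indices", "indptr") %in% ls$name[ls$group == "/mod/atac/X"]))
  # dense matrix seen in observation-major shape
  expect_identical(dim(rhdf5::h5read(f, "mod/rna/X")), c(2L, 3L))
})

test_that("overwriting is atomic and logical content is reproducible", {
  mc <- random_container(2)
  f <- tmp_h5mu()
  write_h5mu(mc, f)
  write_h5mu(mc, f)                       # overwrite in place
  expect_container_equal(mc, read_h5mu(f))
  f2 <- tmp_h5mu()
  write_h5mu(mc, f2)
  expect_container_equal(read_h5mu(f), read_h5mu(f2))
})

test_that("unserialisable uns values are rejected with the key path", {
  mc <- toy_container()
  mc$uns$bad <- function(x) x
  f <- tmp_h5mu()
  expect_error(write_h5mu(mc, f), "uns/bad")
  mc$uns$bad <- NULL
  mc$mod$rna$uns$deep <- list(inner = list(f = mean))
  expect_error(write_h5mu(mc, f), "rna/uns/deep/inner/f")
})

test_that("string columns with missing values are rejected at write", {
  mc <- toy_container()
  mc$obs$label <- c("a", NA, "c", "d")
  mc <- structure(mc, stale = FALSE)
  f <- tmp_h5mu()
  expect_error(write_h5mu(mc, f), "missing values.*factor")
})

test_that("read_modality reads one subtree only", {
  mc <- random_container(4)
  f <- tmp_h5mu()
  write_h5mu(mc, f)
  full <- read_h5mu(f)
  m1 <- names(mc$mod)[1L]
  am <- read_modality(f, m1)
  expect_true(isTRUE(annmatrix_equal(am, full$mod[[m1]])))
  expect_error(read_modality(f, "nope"),
               paste0("file contains: ", paste(names(mc$mod), collapse = ", ")))
  if (length(mc$mod) > 1L) {
    h5_reset_read_stats()
    read_modality(f, m1)
    others <- setdiff(names(mc$mod), m1)
    for (o in others)
      expect_false(any(grepl(paste0("/mod/", o, "/"), h5_read_stats(), fixed = TRUE)))
  }
})

test_that("a modality subtree is standalone-readable at another root", {
  mc <- toy_container()
  f <- tmp_h5mu()
  write_h5mu(mc, f)
  solo <- tempfile(fileext = ".h5")
  withr::defer(unlink(solo))
  rhdf5::h5createFile(solo)
  fid_src <- rhdf5::H5Fopen(f); fid_dst <- rhdf5::H5Fopen(solo)
  for (child in c("X", "layers", "obs", "var", "obsm", "varm", "obsp", "varp", "uns"))
    rhdf5::H5Ocopy(fid_src, paste0("mod/rna/", child), fid_dst, child)
  rhdf5::H5Fclose(fid_src); rhdf5::H5Fclose(fid_dst)
  am <- read_anndata_h5(solo)
  expect_true(isTRUE(annmatrix_equal(am, read_h5mu(f)$mod$rna)))
})

test_that("version and structure problems raise structured errors", {
  f <- tmp_h5mu()
  write_h5mu(toy_container(), f)
  # bump major version
  fid <- rhdf5::H5Fopen(f)
  rhdf5::h5deleteAttribute(fid, "/", "encoding-version")
  obj <- rhdf5::H5Oopen(fid, "/")
  rhdf5::h5writeAttribute("9.0.0", obj, "encoding-version",
                          variableLengthString = TRUE, asScalar = TRUE)
  rhdf5::H5Oclose(obj); rhdf5::H5Fclose(fid)
  err <- tryCatch(read_h5mu(f), error = identity)
  expect_s3_class(err, "mudkit_version_error")
  expect_match(conditionMessage(err), "9.0.0")
  # not HDF5 at all
  txt <- tempfile(); writeLines("not hdf5", txt); withr::defer(unlink(txt))
  expect_s3_class(tryCatch(read_h5mu(txt), error = identity), "mudkit_not_hdf5")
})
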