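test_that("construction computes the union observation axis and axis maps", {
  mc <- toy_container()
  expect_identical(obs_names(mc), c("c1", "c2", "c3", "c4"))
  expect_identical(mc$obsmap$rna, c(1L, 2L, 3L, 0L))
  expect_identical(mc$obsmap$atac, c(0L, 1L, 2L, 3L))
  expect_axis_maps_valid(mc)
})

test_that("a single modality yields identity axes and maps", {
  am <- toy_mod(paste0("c", 1:5), c("g1", "g2"))
  mc <- make_container(list(rna = am))
  expect_identical(obs_names(mc), paste0("c", 1:5))
  expect_identical(mc$obsmap$rna, 1:5)
  expect_identical(var_names(mc), c("g1", "g2"))
})

test_that("colliding feature names are prefixed in the global table only", {
  a <- toy_mod("x", "g1"); b <- toy_mod("x", "g1", seed = 2L)
  mc <- make_container(list(a = a, b = b))
  expect_identical(var_names(mc), c("a:g1", "b:g1"))
  expect_identical(var_names(mc$mod$a), "g1")   # modality-local untouched
  expect_identical(nrow(mc$var), 2L)
})

test_that("invalid modality collections are rejected", {
  am <- toy_mod(c("c1", "c2"), "g1")
  expect_error(make_container(list(am)), "named")
  expect_error(make_container(stats::setNames(list(am, am), c("a", "a"))), "duplicate")
  # duplicated cell names are rejected at modality construction already
  expect_error(
    AnnotatedMatrix(matrix(0, 2, 1, dimnames = list(c("c1", "c1"), "g1"))),
    "duplicate obs_names.*c1")
  expect_error(make_container(list(rna = "not a modality")), "not an AnnotatedMatrix")
})

test_that("update extends the union when a modality is added, and is idempotent", {
  mc <- toy_container()
  extra <- toy_mod(c("c4", "c9"), c("q1",  "q2"), seed = 3L)
  mc2 <- mu_update(set_modality(mc, "prot", extra))
  expect_identical(obs_names(mc2), c("c1", "c2", "c3", "c4", "c9"))
  expect_identical(mc2$obsmap$prot, c(0L, 0L, 0L, 1L, 2L))
  expect_container_equal(mc2, mu_update(mc2))
})

test_that("deleting a modality removes its map and pulled columns", {
  rna <- AnnotatedMatrix(matrix(1:6, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2"))),
                         obs = data.frame(celltype = factor(c("T", "B", "T")),
                                          row.names = paste0("c", 1:3)))
  mc <- make_container(list(rna = rna, atac = toy_mod(paste0("c", 2:4), c("p1", "p2"))))
  expect_true("rna:celltype" %in% colnames(mc$obs))
  mc2 <- mu_update(del_modality(mc, "rna"))
  expect_null(mc2$obsmap$rna)
  expect_false(any(grepl("^rna:", colnames(mc2$obs))))
  expect_identical(obs_names(mc2), paste0("c", 2:4))
})

test_that("pulled modality columns carry missing markers at absent cells", {
  rna <- AnnotatedMatrix(matrix(1:6, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2"))),
                         obs = data.frame(celltype = factor(c("T", "B", "T")),
                                          row.names = paste0("c", 1:3)))
  mc <- make_container(list(rna = rna, atac = toy_mod(paste0("c", 2:4), c("p1", "p2"))))
  pulled <- mc$obs[["rna:celltype"]]
  expect_identical(which(is.na(pulled)), which(mc$obsmap$rna == 0L))
  expect_identical(as.character(pulled[1:3]), c("T", "B", "T"))
})

test_that("update preserves user global columns for surviving names", {
  mc <- toy_container()
  mc$obs$leiden <- c(1L, 2L, 2L, 3L)
  mc2 <- mu_update(set_modality(mc, "atac", toy_mod(c("c2", "c3"), c("p1", "p2"))))
  expect_identical(obs_names(mc2), c("c1", "c2", "c3"))
  expect_identical(mc2$obs$leiden, c(1L, 2L, 2L))
})

test_that("subsetting selects in every modality with recomputed maps", {
  mc <- toy_container()
  s <- subset(mc, obs = c("c2", "c4"))
  expect_identical(obs_names(s), c("c2", "c4"))
  expect_identical(obs_names(s$mod$rna), "c2")
  expect_identical(obs_names(s$mod$atac), c("c2", "c4"))
  expect_identical(s$obsmap$rna, c(1L, 0L))
  expect_identical(s$obsmap$atac, c(1L, 2L))
  expect_axis_maps_valid(s)
})

test_that("a full-mask subset is the identity", {
  mc <- random_container(3)
  s <- subset(mc, obs = rep(TRUE, nrow(mc$obs)))
  expect_container_equal(mc, s)
})

test_that("selector errors name the offenders and reject duplicates", {
  mc <- toy_container()
  expect_error(subset(mc, obs = c("c2", "nope")), "unknown obs names: nope")
  expect_error(subset(mc, obs = c("c2", "c2")), "duplicated")
  expect_error(subset(mc, obs = c(1L, 99L)), "out of range")
  expect_error(subset(mc, var = c("g1", "zzz")), "unknown var names: zzz")
})

test_that("feature subsetting can mix modalities and keeps empty modalities", {
  mc <- toy_container()
  s <- subset(mc, var = c("g2", "p1"))
  expect_identical(var_names(s), c("g2", "p1"))
  expect_identical(var_names(s$mod$rna), "g2")
  s2 <- subset(mc, var = c("p1", "p2"))
  expect_identical(nrow(s2$mod$rna$var), 0L)   # emptied, not dropped
  expect_identical(names(s2$mod), c("rna", "atac"))
})

test_that("subsetting agrees with the independent per-slot oracle", {
  for (seed in 1:20) {
    mc <- random_container(seed)
    sel <- withr::with_seed(seed * 100L, {
      nms <- rownames(mc$obs)
      sample(nms, sample(seq_along(nms), 1))
    })
    got <- subset(mc, obs = sel)
    want <- oracle_subset_obs(mc, sel)
    expect_container_equal(got, want)
    expect_axis_maps_valid(got)
  }
})

test_that("name-selector subsetting composes", {
  for (seed in c(2, 5, 9)) {
    mc <- random_container(seed)
    nms <- rownames(mc$obs)
    s1 <- withr::with_seed(seed, sample(nms, max(3, length(nms) - 2)))
    s2 <- withr::with_seed(seed + 1L, sample(s1, 2))
    expect_container_equal(subset(subset(mc, obs = s1), obs = s2),
                           subset(mc, obs = s2))
  }
})

test_that("intersect_obs keeps exactly the shared observations", {
  mc <- toy_container()
  s <- intersect_obs(mc)
  expect_identical(obs_names(s), c("c2", "c3"))
  same <- make_container(list(a = toy_mod(paste0("c", 1:3), "g1"),
                              b = toy_mod(paste0("c", 1:3), "p1")))
  expect_container_equal(intersect_obs(same), same)
  disjoint <- make_container(list(a = toy_mod("c1", "g1"), b = toy_mod("c2", "p1")))
  expect_warning(s0 <- intersect_obs(disjoint), "empty")
  expect_identical(nrow(s0$obs), 0L)
  expect_identical(names(s0$mod), c("a", "b"))
})

test_that("push and pull move annotation columns through the axis maps", {
  mc <- toy_container()
  mc$obs$leiden <- c("A", "B", "B", "C")
  mc <- push_obs(mc, "leiden")
  expect_identical(mc$mod$rna$obs$leiden, c("A", "B", "B"))
  expect_identical(mc$mod$atac$obs$leiden, c("B", "B", "C"))
  mc2 <- pull_obs(mc, "rna", "leiden")
  expect_identical(mc2$obs[["rna:leiden"]], c("A", "B", "B", NA))
  expect_identical(which(is.na(mc2$obs[["rna:leiden"]])), which(mc2$obsmap$rna == 0L))
  # round-trip for cells present in the modality
  mc3 <- push_obs(mc2, "rna:leiden", overwrite = TRUE)
  expect_identical(mc3$mod$rna$obs[["rna:leiden"]], mc3$mod$rna$obs$leiden)
  expect_error(push_obs(mc, "absent"), "not found")
  expect_error(push_obs(mc, "leiden"), "already exists")
  expect_error(pull_obs(mc, "nope", "leiden"), "unknown modality")
})

test_that("modality mutation flags the container stale until update", {
  mc <- toy_container()
  mc2 <- set_modality(mc, "rna", toy_mod(c("c1", "c7"), c("g1", "g2")))
  expect_true(is_stale(mc2))
  expect_error(subset(mc2, obs = "c1"), "stale")
  mc3 <- mu_update(mc2)
  expect_false(is_stale(mc3))
  # union in first-seen order: the replaced rna modality is scanned first
  expect_identical(obs_names(mc3), c("c1", "c7", "c2", "c3", "c4"))
  expect_false(anyDuplicated(obs_names(mc3)) > 0)
  expect_error(del_modality(mc, "nope"), "unknown modality")
  one <- make_container(list(only = toy_mod("c1", "g1")))
  expect_error(del_modality(one, "only"), "last modality")
})

test_that("nonzero map totals bound the global axis length", {
  for (seed in 4:9) {
    mc <- random_container(seed)
    nz <- vapply(mc$obsmap, function(m) sum(m > 0L), 0L)
    expect_gte(sum(nz), nrow(mc$obs))
    expect_gte(nrow(mc$obs), max(vapply(mc$mod, function(am) nrow(am$obs), 0L)))
  }
})
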