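test_that("rank-sum test reproduces the exact 3-vs-3 enumeration and handles ties", {
  counts <- matrix(c(5, 6, 7, 1, 2, 3), nrow = 1,
                   dimnames = list("OG1", paste0("c", 1:6)))
  ogm <- toy_ogm(counts, setNames(rep(c("in", "out"), each = 3), colnames(counts)))
  # all ingroup values beat all outgroup values: 2 of the 20 equally likely
  # rank assignments are at least this extreme in either direction
  expect_equal(ingroup_outgroup_test(ogm, "OG1", "in"), 0.1)

  tied <- toy_ogm(matrix(rep(4, 6), nrow = 1,
                         dimnames = list("OG1", paste0("c", 1:6))),
                  setNames(rep(c("in", "out"), each = 3), paste0("c", 1:6)))
  expect_equal(ingroup_outgroup_test(tied, "OG1", "in"), 1)

  expect_error(ingroup_outgroup_test(ogm, "OG9", "in"), "OG9")
})

test_that("rank-sum p-values are null-uniform under resampling", {
  set.seed(41)
  p <- replicate(300, {
    counts <- matrix(rnorm(20), nrow = 1, dimnames = list("OG1", paste0("c", 1:20)))
    ogm <- toy_ogm(abs(counts), setNames(rep(c("in", "out"), each = 10),
                                         colnames(counts)))
    ingroup_outgroup_test(ogm, "OG1", "in")
  })
  # exact p-values are discrete, so tied values across replicates are expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("vectorized rank-sum matches wilcox.test row by row under ties", {
  set.seed(43)
  counts <- matrix(rpois(30 * 24, 3), nrow = 30,
                   dimnames = list(sprintf("OG%02d", 1:30), paste0("c", 1:24)))
  in_cols <- rep(c(TRUE, FALSE), each = 12)
  got <- orthocellmap:::rank_sum_p_rows(counts, in_cols)
  ref <- apply(counts, 1, function(v)
    suppressWarnings(wilcox.test(v[in_cols], v[!in_cols], exact = FALSE,
                                 correct = TRUE)$p.value))
  expect_equal(got, unname(ref), tolerance = 1e-10)
})

test_that("shared markers require FC and FDR criteria in both species", {
  set.seed(47)
  make_species <- function(sp, strong_ogs) {
    base <- matrix(rpois(20 * 40, 3), nrow = 20,
                   dimnames = list(sprintf("OG%02d", 1:20),
                                   paste0(sp, "_c", 1:40)))
    types <- setNames(rep(c("ph", "other"), each = 20), colnames(base))
    base[strong_ogs, types == "ph"] <- base[strong_ogs, types == "ph"] + 12
    toy_ogm(base, types, sp)
  }
  oa <- make_species("A", 1:3)
  ob <- make_species("B", c(1:2, 4))   # OG03 strong only in A, OG04 only in B
  fa <- fold_change(celltype_geometric_mean(oa))
  fb <- fold_change(celltype_geometric_mean(ob))
  sm <- shared_markers(fa, fb, "ph", "ph", oa, ob)
  shared <- sm$og[sm$shared]
  expect_setequal(shared, c("OG01", "OG02"))
  # q-values are BH-monotone in p-value rank within each species
  for (col in c("a", "b")) {
    p <- sm[[paste0("p_value_", col)]]; q <- sm[[paste0("q_value_", col)]]
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("marker calls shrink as fc_min or fdr tighten", {
  set.seed(53)
  counts <- matrix(rnbinom(50 * 60, mu = 4, size = 2), nrow = 50,
                   dimnames = list(sprintf("OG%02d", 1:50), paste0("c", 1:60)))
  types <- setNames(rep(c("ph", "o1", "o2"), each = 20), colnames(counts))
  counts[1:10, types == "ph"] <- counts[1:10, types == "ph"] * 3
  ogm <- toy_ogm(counts, types)
  fc <- fold_change(celltype_geometric_mean(ogm))
  loose <- species_markers(fc, ogm, "ph", fc_min = 1.1, fdr = 0.05)
  tight_fc <- species_markers(fc, ogm, "ph", fc_min = 2.0, fdr = 0.05)
  tight_fdr <- species_markers(fc, ogm, "ph", fc_min = 1.1, fdr = 0.001)
  expect_true(all(tight_fc$og[tight_fc$marker] %in% loose$og[loose$marker]))
  expect_true(all(tight_fdr$og[tight_fdr$marker] %in% loose$og[loose$marker]))
})

test_that("UpSet intersections match a brute-force membership-pattern tally", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("b", "c"), s3 = c("b", "c", "d"))
  rep_ <- marker_intersections(sets)
  expect_setequal(rep_$core_set, c("b", "c"))
  expect_equal(sum(rep_$combinations$size),
               length(unique(unlist(sets))))

  disjoint <- marker_intersections(list(x = "a", y = "b"))
  expect_equal(disjoint$core_set, character(0))

  set.seed(59)
  universe <- sprintf("OG%03d", 1:80)
  rnd <- lapply(setNames(1:6, paste0("sp", 1:6)), function(i)
    sample(universe, sample(10:40, 1)))
  got <- marker_intersections(rnd)
  # oracle: tally each OG's membership pattern explicitly
  pat <- sapply(unique(unlist(rnd)), function(og)
    paste(names(rnd)[vapply(rnd, function(s) og %in% s, NA)], collapse = "+"))
  oracle <- table(pat)
  expect_equal(sum(got$combinations$size), length(unique(unlist(rnd))))
  for (k in names(oracle))
    expect_equal(got$combinations$size[got$combinations$combination == k],
                 as.integer(oracle[[k]]))
  expect_setequal(got$core_set,
                  Reduce(intersect, rnd))
})

test_that("conserved-DEG orthogroups count species by explicit loop oracle", {
  path <- write_og_tsv(c("Orthogroup\ts1\ts2\ts3",
                         "OG1\ta1, a2\tb1\tc1",
                         "OG2\ta3\tb2\tc2",
                         "OG3\t\tb3\tc3"))
  tab <- read_orthogroups(path)
  degs <- list(s1 = c("a1"), s2 = c("b1", "b2"), s3 = character(0))
  expect_setequal(conserved_deg_orthogroups(degs, tab, 2), "OG1")
  expect_setequal(conserved_deg_orthogroups(degs, tab, 1), c("OG1", "OG2"))
  expect_equal(conserved_deg_orthogroups(list(s1 = character(0), s2 = character(0)),
                                         tab, 1), character(0))

  set.seed(61)
  big <- random_orthogroup_table(30, c("s1", "s2", "s3", "s4"), p_absent = 0.2)
  all_genes <- lapply(setNames(big$species, big$species), function(sp)
    unlist(lapply(big$membership, `[[`, sp), use.names = FALSE))
  degs2 <- lapply(all_genes, function(g) sample(g, min(10, length(g))))
  got <- suppressMessages(conserved_deg_orthogroups(degs2, big, 3))
  oracle <- big$og_ids[vapply(big$og_ids, function(og) {
    n_sp <- sum(vapply(big$species, function(sp)
      any(big$membership[[og]][[sp]] %in% degs2[[sp]]), NA))
    n_sp >= 3
  }, NA)]
  expect_identical(got, oracle)

  # unmapped DEGs are tallied, not fatal
  expect_message(conserved_deg_orthogroups(list(s1 = "ghost", s2 = "b1", s3 = "c1"),
                                           tab, 1), "map to no orthogroup")
})
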