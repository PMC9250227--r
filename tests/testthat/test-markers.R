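# 10 vs 10 nuclei, one gene fully separated, one null gene: the separated
# configuration has the extreme rank sum in exactly 2 of C(20,10) assignments.
sep_fixture <- function() {
  v <- rbind(
    SEPG = c(rep(5, 10), rep(0, 10)),
    NULLG = rep(c(1, 2), 10),
    BALLAST = rep(100, 20)  # equalizes library sizes across groups
  )
  colnames(v) <- sprintf("n%02d", 1:20)
  lab <- cluster_labeling(colnames(v), rep(c("A", "B"), each = 10))
  list(m = count_matrix(v, "umi_counts"), lab = lab)
}

test_that("a fully separated gene is an exact-enumeration marker", {
  fx <- sep_fixture()
  mk <- find_markers(log_normalize(fx$m), fx$lab, min_lfc = 0.25)
  hit <- mk[mk$gene == "SEPG" & mk$cluster == "A", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$pct_in, 1)
  expect_equal(hit$pct_out, 0)
  expect_equal(hit$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  ## the identically distributed gene is never reported
  expect_false("NULLG" %in% mk$gene)
})

test_that("marker detection is invariant to nucleus order and cluster relabeling", {
  set.seed(21)
  v <- matrix(rpois(30 * 40, 2), 30, 40,
              dimnames = list(paste0("g", 1:30), paste0("n", 1:40)))
  v[1:3, 1:20] <- v[1:3, 1:20] + rpois(60, 6)   # markers of the first group
  lab <- cluster_labeling(colnames(v), rep(c("A", "B"), each = 20))
  m <- log_normalize(count_matrix(v, "umi_counts"))
  base <- find_markers(m, lab)

  perm <- sample(40)
  m2 <- count_matrix(m$values[, perm], "lognorm")
  lab2 <- cluster_labeling(colnames(v)[perm], rep(c("A", "B"), each = 20)[perm])
  shuffled <- find_markers(m2, lab2)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(base), cluster, gene),
    dplyr::arrange(tibble::as_tibble(shuffled), cluster, gene),
    tolerance = 1e-12
  )

  lab3 <- cluster_labeling(colnames(v), rep(c("grp2", "grp1"), each = 20))
  renamed <- find_markers(m, lab3)
  expect_equal(renamed$gene[renamed$cluster == "grp2"],
               base$gene[base$cluster == "A"])
})

test_that("single-nucleus clusters are skipped with a warning", {
  v <- matrix(rpois(60, 3), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("n", 1:6)))
  lab <- cluster_labeling(colnames(v), c("A", "A", "A", "B", "B", "C"))
  expect_warning(
    find_markers(log_normalize(count_matrix(v, "umi_counts")), lab),
    "single-nucleus"
  )
  lab2 <- cluster_labeling(colnames(v), c("A", "A", "A", "A", "A", "C"))
  expect_error(
    suppressWarnings(
      find_markers(log_normalize(count_matrix(v, "umi_counts")), lab2)
    ),
    "fewer than two"
  )
})

test_that("build_signature equals the group-by mean of per-nucleus CPM", {
  set.seed(31)
  v <- matrix(rpois(25 * 12, 5) + 1, 25, 12,
              dimnames = list(paste0("g", 1:25), paste0("n", 1:12)))
  lab <- cluster_labeling(colnames(v), rep(c("A", "B", "C"), each = 4))
  mk <- list(A = c("g1", "g2"), B = c("g3"), C = c("g4", "g5", "g6"))
  S <- build_signature(count_matrix(v, "umi_counts"), lab, mk)

  cpm <- sweep(v, 2, colSums(v), "/") * 1e6
  for (g in c("g1", "g2", "g3", "g4", "g5", "g6")) {
    for (k in c("A", "B", "C")) {
      nuclei <- lab$obs_id[lab$cluster == k]
      expect_equal(S$values[g, k], mean(cpm[g, nuclei]), tolerance = 1e-12)
    }
  }
  ## duplicating every nucleus of a cluster leaves its column unchanged
  v2 <- cbind(v, v[, 1:4])
  colnames(v2) <- c(colnames(v), paste0("dup", 1:4))
  lab2 <- cluster_labeling(colnames(v2), c(as.character(lab$cluster), rep("A", 4)))
  S2 <- build_signature(count_matrix(v2, "umi_counts"), lab2, mk)
  expect_equal(S2$values[, "A"], S$values[, "A"], tolerance = 1e-12)

  ## a single-nucleus cluster column is that nucleus's CPM profile
  lab3 <- cluster_labeling(colnames(v), c("solo", rep("rest", 11)))
  S3 <- build_signature(count_matrix(v, "umi_counts"), lab3, mk)
  expect_equal(S3$values[, "solo"],
               cpm[rownames(S3$values), 1], tolerance = 1e-12)

  expect_error(build_signature(count_matrix(v, "umi_counts"), lab,
                               list(A = "absent_gene")), "absent")
})

test_that("marker genes match across Ensembl version suffixes", {
  v <- matrix(c(8, 1, 1, 8, 4, 4), 3, 2,
              dimnames = list(c("ENSG01.7", "ENSG02.2", "ENSG03"), c("n1", "n2")))
  lab <- cluster_labeling(c("n1", "n2"), c("A", "B"))
  S <- build_signature(count_matrix(v, "umi_counts"), lab,
                       list(A = "ENSG01", B = "ENSG02.99"))
  expect_setequal(rownames(S$values), c("ENSG01.7", "ENSG02.2"))
})

test_that("the bundled fiber marker panel is as published and disjoint", {
  mk <- bundled_fiber_markers()
  expect_true("MYH7B" %in% mk$type_I)
  expect_true("ATP2A1" %in% mk$type_II)
  expect_setequal(mk$type_II, c("ATP2A1", "MYBPC2", "MYH2"))
  all_genes <- unlist(mk)
  expect_equal(anyDuplicated(all_genes), 0L)
})
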