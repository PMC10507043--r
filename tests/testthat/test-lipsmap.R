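tiny_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein = r[[1]], peptide = r[[2]], group = r[[3]],
               replicate = r[[4]], intensity = r[[5]],
               stringsAsFactors = FALSE)))
}

pep_rows <- function(protein, peptide, values_by_group) {
  out <- list()
  for (g in names(values_by_group)) {
    v <- values_by_group[[g]]
    for (i in seq_along(v)) {
      out[[length(out) + 1L]] <- list(protein, peptide, g, i, v[i])
    }
  }
  out
}

test_that("replicate-coverage filter is per-group with an inclusive boundary", {
  tab <- tiny_table(c(
    pep_rows("P1", "a", list(control = 2^c(10, 10, 10, 10),
                             low = 2^c(10, 10, 10, 10),
                             high = 2^c(10, 10, 10, 10))),
    pep_rows("P1", "b", list(control = 2^c(10, 10),
                             low = 2^c(10, 10, 10, 10),
                             high = 2^c(10, 10, 10, 10))),
    pep_rows("P1", "c", list(control = 2^c(10, 10, 10),
                             low = 2^c(10, 10, 10),
                             high = 2^c(10, 10, 10)))))
  kept <- filter_peptides(tab)
  expect_setequal(unique(kept$peptide), c("a", "c"))
})

test_that("differential abundance matches direct computation and an oracle", {
  tab <- tiny_table(c(
    pep_rows("P1", "a", list(control = 2^c(10, 10, 10, 10),
                             high = 2^c(11, 11, 11, 11))),
    pep_rows("P1", "b", list(control = 2^c(10, 10.2, 9.9, 10.1),
                             high = 2^c(10.4, 10.6, 10.3, 10.6)))))
  res <- differential_abundance(tab)
  expect_equal(res$log2fc[res$peptide == "a"], 1)
  # zero variance with different means: p = 0 by the degenerate convention
  expect_equal(res$p[res$peptide == "a"], 0)
  # noisy peptide agrees with stats::t.test to near machine precision
  pb <- res[res$peptide == "b", ]
  tt <- stats::t.test(c(10.4, 10.6, 10.3, 10.6), c(10, 10.2, 9.9, 10.1),
                      var.equal = TRUE)
  expect_equal(pb$p, tt$p.value, tolerance = 1e-12)
  expect_equal(pb$log2fc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)

  # equal constant groups: p = 1 by convention
  tab2 <- tiny_table(pep_rows("P1", "a", list(control = 2^c(10, 10, 10),
                                              high = 2^c(10, 10, 10))))
  expect_equal(differential_abundance(tab2)$p, 1)
})

test_that("seeded noisy tables give p-values identical to an independent t-test", {
  gen <- gen_peptide_table(n_proteins = 20, seed = 77, p_obs = 1)
  res <- differential_abundance(filter_peptides(gen$table))
  pick <- res[sample.int(nrow(res), 25), ]
  for (k in seq_len(nrow(pick))) {
    sub <- gen$table[gen$table$protein == pick$protein[k] &
                       gen$table$peptide == pick$peptide[k], ]
    a <- log2(sub$intensity[sub$group == pick$comparison[k]])
    b <- log2(sub$intensity[sub$group == "control"])
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(pick$p[k], tt$p.value, tolerance = 1e-12)
  }
})

test_that("BH q-values equal a brute-force step-up implementation", {
  p <- c(0.001, 0.01, 0.02, 0.04)
  expect_equal(bh_brute(p), c(0.004, 0.02, 0.02 * 4 / 3, 0.04))
  expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    pv <- stats::runif(stats::rpois(1, 50) + 2)
    expect_equal(stats::p.adjust(pv, "BH"), bh_brute(pv), tolerance = 1e-12)
  }
  # q >= p and q is monotone in p
  pv <- stats::runif(200)
  q <- stats::p.adjust(pv, "BH")
  expect_true(all(q >= pv))
  expect_true(all(diff(q[order(pv)]) >= -1e-15))
})

test_that("interaction calls use the strict one-significant-peptide rule", {
  res <- data.frame(protein = c("P1", "P1", "P2", "P3"),
                    peptide = c("a", "b", "c", "d"),
                    comparison = "high", log2fc = 1,
                    p = c(1e-4, 0.5, 0.02, 0.01),
                    q = c(0.005, 0.5, 0.02, 0.01))
  calls <- call_interactions(res, q_threshold = 0.01)
  expect_true(calls$interacting[calls$protein == "P1"])
  expect_equal(calls$n_significant_peptides[calls$protein == "P1"], 1)
  expect_false(calls$interacting[calls$protein == "P2"])
  # q exactly at the threshold is not significant (strict <)
  expect_false(calls$interacting[calls$protein == "P3"])
})

test_that("ortholog binarization restricts to shared orthologs", {
  calls <- list(
    orgA = data.frame(protein = c("a1", "a2"), comparison = "high",
                      interacting = c(TRUE, FALSE),
                      n_significant_peptides = c(2, 0)),
    orgB = data.frame(protein = c("b1", "b2"), comparison = "high",
                      interacting = c(FALSE, FALSE),
                      n_significant_peptides = 0))
  maps <- list(
    orgA = data.frame(protein = c("a1", "a2", "a3"),
                      ortholog = c("o1", "o2", "o3"), categories = "C"),
    orgB = data.frame(protein = c("b1", "b2"),
                      ortholog = c("o1", "o2"), categories = "C"))
  bm <- ortholog_binary_matrix(calls, maps)
  # o3 is not shared; o2 has no interactions and is dropped
  expect_equal(colnames(bm$matrix), "o1")
  expect_equal(as.numeric(bm$matrix[, "o1"]), c(1, 0))
  expect_setequal(bm$shared_orthologs, c("o1", "o2"))
  expect_error(ortholog_binary_matrix(calls, maps["orgA"]), "no ortholog map")

  # no interactions anywhere: empty matrix after the all-zero-column drop
  calls0 <- lapply(calls, function(d) { d$interacting <- FALSE; d })
  expect_equal(ncol(ortholog_binary_matrix(calls0, maps)$matrix), 0)
})

test_that("interaction PCA matches an eigendecomposition oracle", {
  m <- matrix(c(1, 0, 1, 0, 1, 1, 1, 0, 0), 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), paste0("o", 1:3)))
  pc <- pca_interactions(m)
  ce <- eigen(stats::cov(m))
  expect_equal(abs(pc$scores[, 1]),
               abs(as.numeric(scale(m, scale = FALSE) %*% ce$vectors[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pc$variance_fraction[1],
               ce$values[1] / sum(ce$values), tolerance = 1e-10)
  expect_true(all(diff(pc$fit$sdev) <= 1e-12))

  # identical rows get identical scores
  m2 <- rbind(m, m[1, , drop = FALSE])
  pc2 <- pca_interactions(m2)
  expect_equal(pc2$scores[1, ], pc2$scores[4, ], ignore_attr = TRUE)
})

test_that("category fractions and ward.D2 clustering behave as computed by hand", {
  m <- matrix(c(1, 1, 0,
                0, 1, 0), 2, byrow = TRUE,
              dimnames = list(c("A|met1", "B|met1"), c("o1", "o2", "o3")))
  map <- data.frame(ortholog = c("o1", "o2", "o3"),
                    categories = c("C", "C", "G"))
  hm <- category_heatmap(m, map)
  expect_equal(hm$fractions["C", "A|met1"], 1, ignore_attr = TRUE)
  expect_equal(hm$fractions["C", "B|met1"], 0.5, ignore_attr = TRUE)
  expect_equal(hm$fractions["G", ], c(`A|met1` = 0, `B|met1` = 0))

  # ward.D2 on the line {0, 1, 10, 11} merges {0,1} and {10,11} first
  x <- matrix(c(0, 1, 10, 11), 4, 1,
              dimnames = list(paste0("p", 1:4), "c"))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 2))
  expect_equal(sort(abs(hc$merge[2, ])), c(3, 4))
  # permuting rows leaves the dendrogram topology unchanged
  hm_perm <- category_heatmap(m[c(2, 1), ], map)
  expect_setequal(hm_perm$row_order, hm$row_order)
})

test_that("replicate overlap reproduces the worked mutual-fraction arithmetic", {
  # construct two experiments with |A u B| = 155 and |A n B| = 48
  keys <- sprintf("pep%03d", 1:300)
  qa <- rep(0.5, 300); qb <- rep(0.5, 300)
  qa[1:100] <- 0.001          # A: peptides 1..100
  qb[53:155] <- 0.001         # B: peptides 53..155 -> mutual 53..100 = 48
  resA <- data.frame(protein = "P", peptide = keys, log2fc = stats::rnorm(300),
                     q = qa)
  resB <- data.frame(protein = "P", peptide = keys, log2fc = stats::rnorm(300),
                     q = qb)
  ov <- replicate_overlap(resA, resB, cutoffs = 0.01)
  expect_equal(ov$n_union, 155)
  expect_equal(ov$n_mutual, 48)
  expect_equal(ov$fraction, 48 / 155)
  expect_equal(round(100 * ov$fraction), 31)

  # identical experiments: fraction 1 and perfect correlation
  ov2 <- replicate_overlap(resA, resA, cutoffs = 0.01)
  expect_equal(ov2$fraction, 1)
  expect_equal(ov2$r_log2fc, 1)
  # disjoint significant sets
  ov3 <- replicate_overlap(resA, resB[100:300, ], cutoffs = 1e-6)
  expect_true(is.na(ov3$fraction) || ov3$fraction == 0)
})

test_that("calls are monotone in the cutoff and low-dose calls nest in high-dose", {
  gen <- gen_peptide_table(n_proteins = 150, frac_interacting = 0.2,
                           effect_log2 = 1.5, seed = 91)
  res <- differential_abundance(filter_peptides(gen$table))
  c01 <- call_interactions(res, 0.01)
  c05 <- call_interactions(res, 0.05)
  key <- function(d) paste(d$protein, d$comparison)
  expect_true(all(key(c01)[c01$interacting] %in% key(c05)[c05$interacting]))

  # with the planted high-dose effect dominating, most low-dose interactions
  # are also seen at high dose
  ch <- c05[c05$comparison == "high", ]
  cl <- c05[c05$comparison == "low", ]
  low_hits <- cl$protein[cl$interacting]
  if (length(low_hits) >= 5) {
    frac <- mean(low_hits %in% ch$protein[ch$interacting])
    expect_gt(frac, 0.9)
  }
})
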