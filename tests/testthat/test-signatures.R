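# GMT parsing, TPM normalization and the three signature scorers.

make_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_gmt parses, deduplicates and reports bad lines", {
  p <- make_gmt("HYPOXIA\tdesc\tCA9\tSLC2A1")
  g <- read_gmt(p)
  expect_equal(g$name, "HYPOXIA")
  expect_equal(g$genes[[1]], c("CA9", "SLC2A1"))

  empty <- make_gmt(character())
  expect_equal(nrow(read_gmt(empty)), 0)

  dup <- make_gmt("S1\td\tCA9\tCA9")
  expect_warning(g2 <- read_gmt(dup), "deduplicated")
  expect_equal(g2$genes[[1]], "CA9")

  bad <- make_gmt(c("OK\td\tG1", "SHORT\tonly_two"))
  expect_error(read_gmt(bad), "line 2")
  expect_error(read_gmt(withr::local_tempfile()), "exist")
})

test_that("gene_signature enforces its invariants", {
  expect_error(gene_signature("S", character()), "non-empty")
  expect_error(gene_signature("S", "A", genes_down = "A"), "overlap")
  expect_error(gene_signature("S", "A", scoring = "set_ratio"), "partner")
  expect_warning(gene_signature("S", c("A", "A")), "deduplicated")
})

test_that("counts_to_tpm matches the rate formula and normalizes to 1e6", {
  counts <- matrix(c(10, 20), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- counts_to_tpm(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(as.numeric(tpm), c(1e6 / 3, 2e6 / 3), tolerance = 1e-9)

  single <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.numeric(counts_to_tpm(single, c(g1 = 500))), 1e6)

  # length-weighting: halving a gene's length doubles its rate share
  tpm2 <- counts_to_tpm(counts, c(g1 = 500, g2 = 1000))
  expect_equal(as.numeric(tpm2), c(5e5, 5e5))

  set.seed(1)
  m <- matrix(rpois(60, 50), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  len <- setNames(runif(6, 200, 3000), rownames(m))
  tt <- counts_to_tpm(m, len)
  expect_equal(unname(colSums(tt)), rep(1e6, 10), tolerance = 1e-6)
  # scale invariance within a sample
  expect_equal(counts_to_tpm(m * 2, len), tt, tolerance = 1e-12)

  expect_error(counts_to_tpm(m, len[-1]), "g1")
  m0 <- m; m0[, 3] <- 0
  expect_error(counts_to_tpm(m0, len), "all-zero")
})

test_that("single-gene scores return TPM rows with optional log2", {
  tpm <- matrix(c(5, 50, 500), nrow = 1,
                dimnames = list("EGFR", paste0("s", 1:3)))
  expect_equal(unname(score_single_gene(tpm, "EGFR", log2p1 = TRUE)),
               c(2.585, 5.672, 8.969), tolerance = 1e-3)
  expect_equal(unname(score_single_gene(tpm, "EGFR")), c(5, 50, 500))
  expect_error(score_single_gene(tpm, "FOO"), "FOO")
  zero <- matrix(0, 1, 3, dimnames = list("G", NULL))
  expect_equal(unname(score_single_gene(zero, "G")), c(0, 0, 0))
})

test_that("rank-set scores match the enumeration oracle", {
  set.seed(42)
  expr <- matrix(rnorm(20), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  sig <- gene_signature("S", c("g2", "g4"))
  expect_equal(unname(score_rank_set(expr, sig)),
               rank_set_score_oracle(expr, c("g2", "g4")))
  sig2 <- gene_signature("S2", c("g1", "g3"), genes_down = "g5")
  expect_equal(unname(score_rank_set(expr, sig2)),
               rank_set_score_oracle(expr, c("g1", "g3"), "g5"))
})

test_that("up-genes holding the top ranks give the maximal score", {
  # 10 genes, up-set of 3; put the up-genes at the top in sample 1
  expr <- matrix(c(11:13, 1:7, sample(1:10, 10)), nrow = 10,
                 dimnames = list(paste0("g", 1:10), c("top", "other")))
  sig <- gene_signature("S", c("g1", "g2", "g3"))
  s <- score_rank_set(expr, sig)
  r <- (1:10 - mean(1:10)) / sd(1:10)
  expect_equal(unname(s["top"]), mean(r[8:10]))
  expect_gte(s["top"], s["other"])
})

test_that("rank scores are invariant to strictly monotone per-sample transforms", {
  set.seed(7)
  expr <- matrix(rlnorm(200), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  sig <- gene_signature("S", paste0("g", c(3, 8, 15)),
                        genes_down = paste0("g", c(1, 19)))
  base <- score_rank_set(expr, sig)
  expect_identical(base, score_rank_set(log1p(expr), sig))
  expect_identical(base, score_rank_set(expr^3 + 2, sig))
})

test_that("missing signature genes are dropped or fatal past 50%", {
  set.seed(3)
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  sig <- gene_signature("S", c("g1", "g2", "absent"))
  expect_warning(s <- score_rank_set(expr, sig), "absent")
  expect_equal(unname(s), rank_set_score_oracle(expr, c("g1", "g2")))
  mostly_missing <- gene_signature("S", c("g1", "x1", "x2", "x3"))
  expect_error(suppressWarnings(score_rank_set(expr, mostly_missing)),
               "missing")
  all_missing <- gene_signature("S", c("x1", "x2"))
  expect_error(score_rank_set(expr, all_missing), "missing")
})

test_that("set-ratio scores behave like a contrast", {
  a <- c(s1 = 1, s2 = 2)
  b <- c(s1 = 0, s2 = 1)
  expect_equal(unname(score_set_ratio(a, b)), c(1, 1))
  expect_equal(unname(score_set_ratio(a, a)), c(0, 0))
  expect_error(score_set_ratio(a, b[1]), "length")
  expect_error(score_set_ratio(a, rev(b)), "aligned")
  expect_error(score_set_ratio(a, b, method = "quotient"), "positive")
  expect_equal(score_set_ratio(c(4, 6), c(2, 3), method = "quotient"),
               c(2, 2))
  # anti-correlated components: the contrast tracks the numerator
  set.seed(11)
  x <- rnorm(100)
  a2 <- x + rnorm(100, 0, 0.3)
  b2 <- -x + rnorm(100, 0, 0.3)
  expect_gt(cor(score_set_ratio(a2, b2), a2, method = "spearman"), 0)
})

test_that("score_signatures dispatches all three scorer families", {
  set.seed(5)
  sigs <- list(
    gene_signature("HYPOXIA", paste0("H", 1:10)),
    gene_signature("CD8", paste0("C", 1:8)),
    gene_signature("TREG", paste0("T", 1:8)),
    gene_signature("CD8_TREG", paste0("C", 1:8), scoring = "set_ratio",
                   partner = "TREG"),
    gene_signature("EGFR", "EGFR", scoring = "single_gene")
  )
  genes <- c(paste0("H", 1:10), paste0("C", 1:8), paste0("T", 1:8), "EGFR",
             paste0("B", 1:30))
  expr <- matrix(rpois(length(genes) * 12, 60), nrow = length(genes),
                 dimnames = list(genes, paste0("s", 1:12)))
  out <- score_signatures(expr, sigs)
  expect_named(out, c("sample", "HYPOXIA", "CD8", "TREG", "CD8_TREG",
                      "EGFR"))
  expect_equal(out$CD8_TREG, out$CD8 - out$TREG)
  expect_equal(out$EGFR, unname(expr["EGFR", ]))
  expect_equal(attr(out, "provenance")[["EGFR"]], "TPM")
})
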