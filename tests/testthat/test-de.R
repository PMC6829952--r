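make_expr_2stage <- function(stage0, stage1, stages = c("0", "24")) {
  # stage0/stage1: genes x replicates matrices of FPKM values
  vals <- cbind(stage0, stage1)
  rownames(vals) <- paste0("g", seq_len(nrow(vals)))
  tiny_expr(vals, stages = stages, reps = ncol(stage0))
}

test_that("stage means apply the pseudo-count and average replicates", {
  e <- make_expr_2stage(matrix(c(10, 20, 30), 1), matrix(c(1, 1, 1), 1))
  expect_equal(unname(stage_means(e, "0", pseudocount = 0)), 20)
  expect_equal(unname(stage_means(e, "0", pseudocount = 0.5)), 20.5)
  # all-zero gene with k = 0.5 has mean exactly 0.5
  z <- make_expr_2stage(matrix(0, 1, 3), matrix(0, 1, 3))
  expect_equal(unname(stage_means(z, "0", pseudocount = 0.5)), 0.5)
  expect_error(stage_means(e, "999"), "unknown stage")
})

test_that("signal statistics follow their closed forms", {
  e <- make_expr_2stage(matrix(c(10, 10, 10,  7, 7, 7,  20, 20, 20), 3, byrow = TRUE),
                        matrix(c(40, 40, 40,  7, 7, 7,   5,  5,  5), 3, byrow = TRUE))
  s <- signal_statistics(e, list(test = "24", ref = "0"), pseudocount = 0)
  expect_equal(s$M, c(2, 0, -2))
  expect_equal(s$D, c(30, 0, 15))
})

test_that("noise distribution pools within-stage replicate pairs", {
  set.seed(1)
  G <- 7
  e <- make_expr_2stage(matrix(rlnorm(G * 3), G), matrix(rlnorm(G * 3), G))
  ct <- list(test = "24", ref = "0")
  noise <- noise_distribution(e, ct)
  expect_equal(nrow(noise), 2 * choose(3, 2) * G)
  expect_true(all(noise$m >= 0 & noise$d >= 0))

  # identical replicates give an all-zero noise cloud
  flat <- make_expr_2stage(matrix(5, 2, 3), matrix(9, 2, 3))
  expect_true(all(noise_distribution(flat, ct) == 0))

  # invariant to replicate ordering
  perm <- e
  ids <- stage_samples(e, "0")
  perm$values[, ids] <- perm$values[, rev(ids)]
  n2 <- noise_distribution(perm, ct)
  key <- function(x) paste(sort(paste(signif(x$m, 12), signif(x$d, 12))))
  expect_identical(key(noise), key(n2))

  single <- tiny_expr(matrix(1:4, 2, dimnames = list(c("g1", "g2"), NULL)),
                      stages = c("0", "24"), reps = 1)
  expect_error(noise_distribution(single, ct), "single replicate")
})

test_that("DE probability counts strictly dominated noise points", {
  # 10 noise points, exactly 8 strictly dominated by the first gene
  noise <- data.frame(m = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 2.0, 1.5),
                      d = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100))
  signal <- data.frame(gene_id = c("a", "b", "c"),
                       M = c(1.0, 9, 0), D = c(50, 1000, 0))
  p <- de_probability(signal, noise)
  expect_equal(p[1], 8 / 10)   # brute-force count: 8 of 10 dominated
  expect_equal(p[2], 1)        # dominates every noise point
  expect_equal(p[3], 0)        # (0, 0): nothing strictly below
  expect_equal(p, brute_de_probability(signal, noise))
})

test_that("DE probability matches brute force on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    noise <- data.frame(m = round(abs(rnorm(200)), 2),
                        d = round(abs(rnorm(200, sd = 10)), 1))
    signal <- data.frame(gene_id = sprintf("g%02d", 1:50),
                         M = rnorm(50), D = abs(rnorm(50, sd = 10)))
    expect_equal(de_probability(signal, noise),
                 brute_de_probability(signal, noise))
  }
})

test_that("probability is monotone in |M| and D at fixed noise", {
  set.seed(3)
  noise <- data.frame(m = abs(rnorm(300)), d = abs(rnorm(300)))
  M <- seq(0, 3, by = 0.25)
  pM <- de_probability(data.frame(gene_id = seq_along(M), M = M, D = 1), noise)
  expect_true(all(diff(pM) >= 0))
  D <- seq(0, 3, by = 0.25)
  pD <- de_probability(data.frame(gene_id = seq_along(D), M = 1, D = D), noise)
  expect_true(all(diff(pD) >= 0))
})

test_that("swapping test and reference negates M, keeps D and probability", {
  set.seed(8)
  G <- 40
  e <- make_expr_2stage(matrix(rlnorm(G * 3, 3), G), matrix(rlnorm(G * 3, 3), G))
  fwd <- run_de(e, data.frame(test = "24", ref = "0", system = "fixed",
                              contrast_id = "24_vs_0"))
  rev <- run_de(e, data.frame(test = "0", ref = "24", system = "fixed",
                              contrast_id = "0_vs_24"))
  expect_equal(rev$M, -fwd$M)
  expect_equal(rev$D, fwd$D)
  expect_equal(rev$probability, fwd$probability)
  expect_identical(rev$call[fwd$call == "up"],
                   rep("down", sum(fwd$call == "up")))
  expect_identical(rev$call[fwd$call == "down"],
                   rep("up", sum(fwd$call == "down")))
})

test_that("calls respect the inclusive fold-change and probability thresholds", {
  expect_identical(call_de(1, 0.8), "up")        # FC exactly 2, p exactly 0.8
  expect_identical(call_de(2, 0.79), "ns")
  expect_identical(call_de(-3, 0.95), "down")
  expect_identical(call_de(0.99, 0.99), "ns")
  expect_identical(call_de(-1, 0.8), "down")
})

test_that("external DE calls are validated on read", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontrast_id\tcall", "g1\tc1\tup", "g2\tc1\tns"), p)
  x <- read_de_calls(p)
  expect_identical(x$call, c("up", "ns"))
  writeLines(c("gene_id\tcontrast_id\tcall", "g1\tc1\tmaybe"), p)
  expect_error(read_de_calls(p), "unknown call")
})
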