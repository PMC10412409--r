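test_that("detected_genes_from_rna counts genes with at least one read", {
  rna <- rbind(a = c(0, 0, 3, 1), b = c(1, 1, 1, 0))
  expect_identical(detected_genes_from_rna(rna), c(a = 2L, b = 3L))
  expect_identical(detected_genes_from_rna(Matrix::Matrix(rna, sparse = TRUE)),
                   c(a = 2L, b = 3L))
  rna0 <- rbind(a = c(1, 2), dead = c(0, 0))
  expect_error(detected_genes_from_rna(rna0), "dead")
})

test_that("HashingExperiment enforces its invariants", {
  counts <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_s3_class(HashingExperiment(counts, c(10, 20)), "HashingExperiment")
  expect_error(HashingExperiment(counts, c(10, 0)), "zero detected genes")
  expect_error(HashingExperiment(counts, c(10, 20, 30)), "one entry per")
  expect_error(HashingExperiment(matrix(c(-1, 2, 3, 4), 2, 2), c(1, 1)),
               "non-negative")
  expect_error(HashingExperiment(matrix(c(1.5, 2, 3, 4), 2, 2), c(1, 1)),
               "non-negative integers")
  expect_error(HashingExperiment(counts, c(10, 20),
                                 droplet_ids = c("a", "a")), "unique")
  expect_error(HashingExperiment(counts[1, , drop = FALSE], 10), "2 droplets")
})

test_that("initial_clusters separates clear positive/negative counts", {
  y <- c(1, 2, 1, 2, 500, 600, 550)
  expect_identical(initial_clusters(y, seed = 1),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(initial_clusters(c(0, 0, 1000), seed = 1),
                   c(FALSE, FALSE, TRUE))
  expect_error(initial_clusters(rep(5, 10), seed = 1), "no variation")
})

test_that("initial_clusters recovers well-separated NB components", {
  # oracle: threshold at the midpoint of the component log-means
  d <- sample_naive_mixture(2000, mu1 = 20, nu1 = 5, mu2 = 2000, nu2 = 10,
                            pi2 = 0.4, seed = 11)
  pos <- initial_clusters(d$y, seed = 11)
  oracle <- log1p(d$y) > (log(20) + log(2000)) / 2
  expect_gte(mean(pos == oracle), 0.99)
  expect_gte(mean(pos == (d$z == 1)), 0.99)
})

test_that("initial_clusters is permutation-equivariant and seeded", {
  d <- sample_naive_mixture(500, 10, 5, 800, 10, 0.3, seed = 2)
  pos <- initial_clusters(d$y, seed = 5)
  expect_identical(pos, initial_clusters(d$y, seed = 5))
  set.seed(1); perm <- sample(length(d$y))
  expect_identical(initial_clusters(d$y[perm], seed = 5), pos[perm])
})

test_that("flag_outliers applies the Tukey fence per rule", {
  y <- c(10:17, 1000)
  pos <- rep(TRUE, 9)
  x <- rep(100, 9)
  expect_identical(flag_outliers(y, x, pos),
                   c(rep(FALSE, 8), TRUE))
  # degenerate IQR: equal positive counts flag nothing on y
  expect_false(any(flag_outliers(rep(50, 9), x, pos)))
  # gene-count outliers are flagged across both clusters
  x2 <- c(rep(100, 99), 10000)
  out <- flag_outliers(rep(1, 100), x2, rep(FALSE, 100))
  expect_identical(which(out), 100L)
  # a droplet sitting at both medians is never flagged
  y3 <- c(1, 2, 3, 4, 5); x3 <- c(9, 10, 11, 12, 13)
  expect_false(flag_outliers(y3, x3, rep(TRUE, 5))[3])
})

test_that("Matrix Market writer/reader round-trips counts exactly", {
  sim <- generate_dataset(m = 60, n = 3, seed = 4)
  dir <- withr::local_tempdir()
  write_hashing_mtx(sim$experiment, dir)
  hx <- read_hashing_mtx(dir, detected_genes = file.path(dir, "genes.tsv"))
  expect_identical(hx$counts, sim$experiment$counts)
  expect_identical(hx$detected_genes, sim$experiment$detected_genes)
  expect_identical(hx$hto_names, sim$experiment$hto_names)
})

test_that("mtx reader auto-detects orientation and rejects ambiguity", {
  sim <- generate_dataset(m = 40, n = 3, seed = 5)
  dir <- withr::local_tempdir()
  write_hashing_mtx(sim$experiment, dir)
  # droplets x features orientation is also accepted
  Matrix::writeMM(Matrix::Matrix(sim$experiment$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  hx <- read_hashing_mtx(dir, detected_genes = file.path(dir, "genes.tsv"))
  expect_identical(hx$counts, sim$experiment$counts)
  # square matrix with equal sidecar counts is ambiguous
  sq <- generate_dataset(m = 3, n = 3, seed = 6,
                         class_probs = list(msm = 0, negative = 0))
  write_hashing_mtx(sq$experiment, dir)
  expect_error(read_hashing_mtx(dir,
                                detected_genes = file.path(dir, "genes.tsv")),
               "ambiguous")
})

test_that("mtx reader selects HTO features by type and computes genes", {
  # mixed matrix: 5 gene-expression features + 2 antibody-capture features
  set.seed(8)
  genes <- matrix(rpois(50 * 5, 2), 50, 5)
  genes[, 1] <- genes[, 1] + 1  # every droplet detects at least one gene
  htos <- matrix(rpois(50 * 2, 40), 50, 2)
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(t(cbind(genes, htos)), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(sprintf("bc%02d", 1:50), file.path(dir, "barcodes.tsv"))
  feats <- data.frame(id = c(paste0("G", 1:5), "HTO_A", "HTO_B"),
                      name = c(paste0("G", 1:5), "HTO_A", "HTO_B"),
                      type = c(rep("Gene Expression", 5),
                               rep("Antibody Capture", 2)))
  data.table::fwrite(feats, file.path(dir, "features.tsv"),
                     col.names = FALSE, sep = "\t")
  hx <- read_hashing_mtx(dir)
  expect_identical(hx$hto_names, c("HTO_A", "HTO_B"))
  expect_identical(unname(hx$detected_genes),
                   as.integer(rowSums(genes > 0)))
  # selection by explicit name works too
  hx2 <- read_hashing_mtx(dir, hto_names = "HTO_B")
  expect_identical(unname(hx2$counts[, 1]), htos[, 2])
})

test_that("dense table reader matches the mtx reader", {
  sim <- generate_dataset(m = 30, n = 2, seed = 9)
  dir <- withr::local_tempdir()
  tab <- data.frame(droplet_id = sim$experiment$droplet_ids,
                    sim$experiment$counts,
                    detected_genes = sim$experiment$detected_genes)
  data.table::fwrite(tab, file.path(dir, "counts.tsv"), sep = "\t")
  hx <- read_hashing_table(file.path(dir, "counts.tsv"),
                           detected_genes = "detected_genes")
  expect_identical(hx$counts, sim$experiment$counts)
  expect_identical(hx$detected_genes, sim$experiment$detected_genes)
})
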