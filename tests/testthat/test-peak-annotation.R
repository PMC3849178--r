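test_that("posterior filter keeps strictly greater peaks", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                      end = c(5, 15, 25), name = c("a", "b", "c"),
                      posterior = c(0.95, 0.9, 0.89))
  expect_equal(filter_peaks(peaks)$name, "a")
  expect_equal(nrow(filter_peaks(peaks, 0.5)), 3L)
})

test_that("peaks map to the nearest TSS within the window", {
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    strand = "+", tss = c(1100L, 50000L),
                    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 1000L, end = 1200L,
                      name = "p1", posterior = 1)
  a <- assign_peaks(peaks, tss)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$distance, 0L)
})

test_that("window boundary is inclusive at exactly window_bp and excludes beyond", {
  tss <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
                    tss = 0L, stringsAsFactors = FALSE)
  # midpoint 20 001 from the only TSS -> unassigned
  peaks <- data.frame(chrom = "chr1", start = 20001L - 50L,
                      end = 20001L + 50L, name = "far", posterior = 1)
  expect_equal(nrow(assign_peaks(peaks, tss, 20000)), 0L)
  peaks$start <- 19950L; peaks$end <- 20050L   # midpoint exactly 20 000
  expect_equal(nrow(assign_peaks(peaks, tss, 20000)), 1L)
})

test_that("nearest rule wins and equidistant ties pick the smaller gene id", {
  tss <- data.frame(gene_id = c("gNear", "gFar"), chrom = "chr1",
                    strand = "+", tss = c(14999L, 5000L),
                    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 9950L, end = 10050L,
                      name = "p", posterior = 1)   # midpoint 10 000
  expect_equal(assign_peaks(peaks, tss)$gene_id, "gNear")  # 4999 vs 5000
  tss$tss <- c(9000L, 11000L)                      # both 1000 away
  expect_equal(assign_peaks(peaks, tss)$gene_id, "gFar")   # lexicographic
  expect_error(assign_peaks(peaks, tss[0, ]), "empty")
})

test_that("assigned-gene count is monotone in the window size", {
  set.seed(42)
  tss <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                    strand = "+", tss = sort(sample.int(1e6, 20)),
                    stringsAsFactors = FALSE)
  mid <- sample.int(1e6, 50)
  peaks <- data.frame(chrom = "chr1", start = mid - 50L, end = mid + 50L,
                      name = sprintf("p%02d", 1:50), posterior = 1)
  windows <- c(1000, 5000, 20000, 100000)
  counts <- vapply(windows, function(w) {
    a <- assign_peaks(peaks, tss, w)
    expect_true(all(a$distance <= w))
    length(unique(a$gene_id))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("promoter binding marks >= 1 bp overlap with the +/-500 window", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 1000L, stringsAsFactors = FALSE)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  name = "p", posterior = 1)
  expect_equal(promoter_binding(list(TF = pk(900L, 1100L)), tss)["g1", "TF"], 1L)
  expect_equal(promoter_binding(list(TF = pk(0L, 100L)), tss)["g1", "TF"], 0L)
  # peak covering only position tss+500 still overlaps
  expect_equal(promoter_binding(list(TF = pk(1500L, 1501L)), tss)["g1", "TF"], 1L)
  # one past the window end does not
  expect_equal(promoter_binding(list(TF = pk(1501L, 1502L)), tss)["g1", "TF"], 0L)
})

test_that("promoter binding is order-independent in peaks and TFs", {
  set.seed(7)
  tss <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                    strand = "+", tss = seq(1000L, 91000L, by = 10000L),
                    stringsAsFactors = FALSE)
  mk <- function() {
    s <- sample(seq(0L, 95000L, by = 500L), 8)
    data.frame(chrom = "chr1", start = s, end = s + 400L,
               name = sprintf("p%d", seq_along(s)), posterior = 1)
  }
  tfs <- list(A = mk(), B = mk())
  b1 <- promoter_binding(tfs, tss)
  b2 <- promoter_binding(rev(tfs), tss)
  for (tf in names(tfs)) {
    sh <- tfs[[tf]][sample(nrow(tfs[[tf]])), ]
    tfs[[tf]] <- sh
  }
  b3 <- promoter_binding(tfs, tss)
  expect_equal(b1, b2[, colnames(b1)])
  expect_equal(b1, b3)
})

test_that("read-count correlation matches the closed form on log scale", {
  counts <- cbind(lib1 = c(1, 2, 3, 10), lib2 = c(3, 2, 1, 9),
                  lib3 = c(2, 4, 6, 20))
  cc <- correlation_clusters(counts)
  expect_equal(diag(cc$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$correlation, t(cc$correlation))
  expect_equal(cc$correlation["lib1", "lib2"],
               pearson_direct(log2(counts[, 1] + 1), log2(counts[, 2] + 1)))
  # scaling a library shifts its log profile -> correlation unchanged = 1
  cc2 <- correlation_clusters(cbind(a = c(2, 4, 8, 16), b = c(4, 8, 16, 32)))
  expect_equal(cc2$correlation["a", "b"], 1, tolerance = 1e-3)
  expect_error(correlation_clusters(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
})
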