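cs <- c(chr1 = 1e5, chr2 = 1e5)

test_that("read_bedgraph parses, sorts, merges and computes wigsum", {
  f <- write_lines_tmp("chr1\t0\t10\t2.0")
  tr <- read_bedgraph(f, cs)
  expect_equal(tr$wigsum, 20)
  expect_equal(nrow(tr$intervals), 1)

  f <- write_lines_tmp(character(0))
  tr <- read_bedgraph(f, cs)
  expect_equal(tr$wigsum, 0)
  expect_equal(nrow(tr$intervals), 0)

  # shuffled non-overlapping lines: sorted output, hand-summed wigsum
  f <- write_lines_tmp(c("chr1\t50\t60\t1.5",
                         "chr1\t0\t10\t2.0",
                         "chr1\t20\t40\t0.5"))
  tr <- read_bedgraph(f, cs)
  expect_equal(tr$intervals$start, c(0, 20, 50))
  expect_equal(tr$wigsum, 2.0 * 10 + 0.5 * 20 + 1.5 * 10)

  # track lines tolerated; book-ended equal values merged
  f <- write_lines_tmp(c("track type=bedGraph", "chr1\t0\t10\t1",
                         "chr1\t10\t30\t1", "chr1\t30\t40\t2"))
  tr <- read_bedgraph(f, cs)
  expect_equal(tr$intervals$start, c(0, 30))
  expect_equal(tr$intervals$end, c(30, 40))
  expect_equal(tr$wigsum, 30 + 20)
})

test_that("read_bedgraph rejects malformed input with line numbers", {
  f <- write_lines_tmp(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"))
  expect_error(read_bedgraph(f, cs), "line 2.*overlap")
  f <- write_lines_tmp("chrUn\t0\t10\t1")
  expect_error(read_bedgraph(f, cs), "unknown chromosome")
  f <- write_lines_tmp("chr1\t0\t10\tNOPE")
  expect_error(read_bedgraph(f, cs), "non-numeric")
})

test_that("bedGraph round trip preserves covered intervals", {
  f <- write_lines_tmp(c("chr1\t5\t25\t1.25", "chr2\t0\t10\t-0.5",
                         "chr1\t30\t41\t3"))
  tr <- read_bedgraph(f, cs)
  f2 <- tempfile()
  write_bedgraph(tr, f2)
  tr2 <- read_bedgraph(f2, cs)
  expect_equal(tr2$intervals, tr$intervals)
  expect_equal(tr2$wigsum, tr$wigsum)
})

test_that("normalize_track scales to the target wigsum and is idempotent", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 25e6,
                                  value = 2),
                       c(chr1 = 30e6))
  expect_equal(tr$wigsum, 5e7)
  n1 <- normalize_track(tr, 1e8)
  expect_equal(n1$intervals$value, 4)

  # already at target: identical values
  expect_equal(normalize_track(n1, 1e8)$intervals$value, n1$intervals$value)

  set.seed(4)
  iv <- data.frame(chrom = "chr1", start = seq(0, 900, by = 100),
                   end = seq(0, 900, by = 100) + sample(10:90, 10),
                   value = runif(10, 0.1, 5))
  tr <- coverage_track(iv, cs)
  n <- normalize_track(tr)
  expect_equal(sum(n$intervals$value * (n$intervals$end - n$intervals$start)),
               1e8, tolerance = 1e-9)
  n2 <- normalize_track(n)
  expect_equal(n2$intervals$value, n$intervals$value, tolerance = 1e-9)

  empty <- coverage_track(iv[0, ], cs)
  expect_error(normalize_track(empty), "cannot normalize empty track")
})

test_that("read_regions anchors at the TSS and enforces bounds", {
  f <- write_lines_tmp(c("chr1\t1000\t2000\tgplus\tpc\t+",
                         "chr1\t1000\t2000\tgminus\tpc\t-",
                         "chr1\t100\t300\tgnear\tpc\t+"))
  expect_message(rg <- read_regions(f, 500, cs), "1 region\\(s\\) dropped")
  e <- rg$entries
  expect_equal(e$region_id, c("gplus", "gminus"))
  expect_equal(e$anchor[e$region_id == "gplus"], 1000) # window [500, 1500)
  expect_equal(e$anchor[e$region_id == "gminus"], 1999) # window [1499, 2499)

  # duplicate (chrom, anchor, strand) dropped keeping the first
  f <- write_lines_tmp(c("chr1\t1000\t2000\ta\tpc\t+",
                         "chr1\t1000\t3000\tb\tpc\t+"))
  expect_message(rg <- read_regions(f, 500, cs), "duplicate")
  expect_equal(rg$entries$region_id, "a")

  f <- write_lines_tmp("chr1\t1000\t2000\ta\tpc\t*")
  expect_error(read_regions(f, 500, cs), "malformed strand")
  f <- write_lines_tmp(c("chr1\t1000\t2000\ta\tpc\t+",
                         "chr1\t5000\t6000\ta\tpc\t+"))
  expect_error(read_regions(f, 500, cs), "duplicate region_id")
})

test_that("filter_blacklist removes >=1 bp overlaps, half-open", {
  rg <- region_set(data.frame(region_id = "r1", chrom = "chr1",
                              anchor = 1000, strand = "+",
                              class_label = "pc"), 500)
  # window [500, 1500): blacklist touching base 1499 overlaps
  out <- filter_blacklist(rg, data.frame(chrom = "chr1", start = 1499,
                                         end = 1600))
  expect_equal(nrow(out$entries), 0)
  # [1500, 1600) does not overlap [500, 1500)
  out <- filter_blacklist(rg, data.frame(chrom = "chr1", start = 1500,
                                         end = 1600))
  expect_equal(nrow(out$entries), 1)
})

test_that("filter_blacklist matches a brute-force overlap check", {
  set.seed(7)
  anchors <- seq(1000, 10000, by = 1000)
  rg <- region_set(data.frame(region_id = paste0("r", 1:10),
                              chrom = "chr1", anchor = anchors,
                              strand = rep(c("+", "-"), 5),
                              class_label = "pc"), 400)
  bl <- data.frame(chrom = "chr1",
                   start = c(1500, 4990, 8000), end = c(1700, 5100, 8010))
  out <- filter_blacklist(rg, bl, exclude_ids = "r10")
  overlaps <- sapply(anchors, function(a) {
    any(pmax(a - 400, bl$start) < pmin(a + 400, bl$end))
  })
  keep_expected <- !overlaps & paste0("r", 1:10) != "r10"
  expect_equal(out$entries$region_id, paste0("r", 1:10)[keep_expected])
  expect_equal(sum(keep_expected), 6)
  # subset of input, idempotent
  expect_true(all(out$entries$region_id %in% rg$entries$region_id))
  expect_identical(filter_blacklist(out, bl, "r10")$entries, out$entries)
})

test_that("extract_profiles bins correctly and reverses minus strand", {
  rg <- region_set(data.frame(region_id = c("p", "m"), chrom = "chr1",
                              anchor = c(1000, 3000), strand = c("+", "-"),
                              class_label = "pc"), 50)
  const <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 5000,
                                     value = 3), cs)
  pm <- extract_profiles(const, rg, 10)
  expect_true(all(pm$values == 3))
  expect_equal(pm$grid, seq(-50, 40, by = 10))

  # signal only in the most-downstream bin of each region:
  # + region: genomic [1040,1050); - region: genomic [2950,2960)
  tr <- coverage_track(data.frame(chrom = "chr1",
                                  start = c(1040, 2950),
                                  end = c(1050, 2960), value = 7), cs)
  pm <- extract_profiles(tr, rg, 10)
  expect_equal(pm$values[1, ], c(rep(0, 9), 7)) # + strand: last column
  expect_equal(pm$values[2, ], c(rep(0, 9), 7)) # - strand: reversed too
  pm_un <- extract_profiles(tr, rg, 10, oriented = FALSE)
  expect_equal(pm_un$values[2, ], c(7, rep(0, 9))) # genome orientation

  # hand-computed bin means with partial overlaps, bin 5
  rg2 <- region_set(data.frame(region_id = "h", chrom = "chr1",
                               anchor = 100, strand = "+",
                               class_label = "pc"), 10)
  tr2 <- coverage_track(data.frame(chrom = "chr1", start = c(88, 97),
                                   end = c(93, 112), value = c(2, 4)), cs)
  pm2 <- extract_profiles(tr2, rg2, 5)
  # windows [90,95): bases 90-92 value 2 -> 6/5; [95,100): 97-99 value 4;
  # [100,105): all 4; [105,110): 105-111 -> bases 105..109 value 4
  expect_equal(pm2$values[1, ], c(6 / 5, 12 / 5, 4, 4))
})

test_that("extract_profiles warns on missing chromosome, zero rows", {
  rg <- region_set(data.frame(region_id = c("a", "b"),
                              chrom = c("chr1", "chrX"),
                              anchor = c(1000, 1000),
                              strand = "+", class_label = "pc"), 50)
  tr <- coverage_track(data.frame(chrom = "chr1", start = 900, end = 1100,
                                  value = 1), cs)
  expect_warning(pm <- extract_profiles(tr, rg, 10), "chrX")
  expect_true(all(pm$values[2, ] == 0))
  expect_true(all(pm$values[1, ] == 1))
})

test_that("profiles of a strand-symmetric track are strand-flip invariant", {
  # symmetric coverage around each anchor
  rg <- region_set(data.frame(region_id = c("a", "b"), chrom = "chr1",
                              anchor = c(1000, 3000),
                              strand = c("+", "-"), class_label = "pc"), 50)
  iv <- do.call(rbind, lapply(c(1000, 3000), function(a)
    data.frame(chrom = "chr1", start = c(a - 30, a + 20),
               end = c(a - 20, a + 30), value = 5)))
  tr <- coverage_track(iv, cs)
  pm1 <- extract_profiles(tr, rg, 10)
  rg_flip <- rg
  rg_flip$entries$strand <- c("-", "+")
  pm2 <- extract_profiles(tr, rg_flip, 10)
  expect_equal(pm1$values, pm2$values)
})

test_that("profile matrix TSV round trip", {
  pm <- profile_matrix(matrix(rnorm(12), 3, 4), c("a", "b", "c"),
                       c(-20, -10, 0, 10))
  f <- tempfile()
  write_profile_matrix(pm, f)
  pm2 <- read_profile_matrix(f)
  expect_equal(pm2$region_ids, pm$region_ids)
  expect_equal(pm2$grid, pm$grid)
  expect_equal(pm2$values, pm$values, tolerance = 1e-12)
})
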