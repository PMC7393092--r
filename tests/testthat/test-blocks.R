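test_that("summary-statistics reader validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "1", "2"),
    BP = c(100, 200, 300), P = c(1e-6, 0.2, 1)), tf)
  ss <- read_summary_stats(tf)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$p_value, c(1e-6, 0.2, 1))

  # NA / out-of-range p-values are rejected with the file line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2"), CHR = "1", BP = c(1, 2),
    P = c("NA", "0.5")), bad)
  expect_error(read_summary_stats(bad), "line\\(s\\): 2",
               class = "epifinemap_validation_error")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = "rs1", CHR = "1", BP = 1, P = 1.5), bad2)
  expect_error(read_summary_stats(bad2),
               class = "epifinemap_validation_error")

  # missing column is a format error naming it
  bad3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(SNP = "rs1", CHR = "1", BP = 1), bad3)
  expect_error(read_summary_stats(bad3), "P",
               class = "epifinemap_format_error")

  # files written by the synthetic generator round-trip losslessly
  d <- generate_dataset(synth_config(n_blocks = 4, snps_per_block = 6,
                                     n_features = 5, n_causal_features = 2,
                                     n_causal_blocks = 2, seed = 11),
                        withr::local_tempdir())
  ss2 <- read_summary_stats(d$paths$sumstats)
  expect_equal(nrow(ss2), 24)
  back <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(SNP = ss2$snp_id, CHR = ss2$chrom,
                                  BP = ss2$pos, P = ss2$p_value), back)
  expect_equal(read_summary_stats(back), ss2)
})

test_that("lead selection is greedy with 1 Mb exclusion and matches the
           brute-force oracle on random inputs", {
  ss <- make_sumstats("1", c(1e6, 1.5e6, 3e6), c(1e-9, 1e-7, 1e-6))
  leads <- select_lead_snps(ss)
  expect_equal(leads$pos, c(1e6, 3e6))

  # single qualifying SNP
  one <- make_sumstats("1", c(5, 10), c(1e-5, 0.5))
  expect_equal(select_lead_snps(one)$pos, 5)

  # nothing qualifies -> empty, not an error
  expect_equal(nrow(select_lead_snps(make_sumstats("1", 1, 0.1))), 0)

  # equal minimal p: lower (chrom, pos) wins, in either input order
  tie <- make_sumstats(c("2", "1"), c(100, 200), c(1e-6, 1e-6))
  expect_equal(select_lead_snps(tie)$chrom[1], "1")
  expect_equal(select_lead_snps(tie[2:1, ])$chrom[1], "1")

  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(20:120, 1)
      ss <- make_sumstats(
        chrom = sample(1:4, n, replace = TRUE),
        pos = sample(1:5e6, n),
        p = 10^runif(n, -10, 0))
      got <- select_lead_snps(ss)
      want <- oracle_leads(ss)
      expect_equal(got$snp_id, want$snp_id)
      # selected leads on one chromosome are > 1 Mb apart
      for (ch in unique(got$chrom)) {
        p <- sort(got$pos[got$chrom == ch])
        if (length(p) > 1) expect_true(all(diff(p) > 1e6))
      }
    }
  })
})

test_that("block construction caps membership, keeps blocks disjoint and
           assigns shared SNPs to the stronger lead", {
  # 200 qualifying neighbors -> exactly 30 members
  withr::with_seed(7, {
    ss <- make_sumstats("1", c(5e6, 5e6 + sample(c(-2500:-1, 1:2500), 200) * 100),
                        c(1e-9, 10^runif(200, -8, log10(5e-4))))
  })
  blocks <- build_blocks(ss, select_lead_snps(ss))
  expect_equal(nrow(blocks), 30)
  expect_equal(sum(blocks$is_lead), 1)
  # retained members are the most significant neighbors
  kept_p <- sort(blocks$p_value)
  expect_equal(kept_p, sort(ss$p_value)[1:30])

  # zero qualifying neighbors -> singleton block
  lone <- make_sumstats("1", c(100, 2e7), c(1e-8, 0.9))
  b1 <- build_blocks(lone, select_lead_snps(lone))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$weight, 10)

  # two leads 1.2 Mb apart: shared candidates end up in exactly one block
  ss2 <- make_sumstats(
    "1", c(1e6, 2.2e6, 1.4e6, 1.6e6, 1.8e6, 2.0e6),
    c(1e-9, 1e-8, 1e-4, 2e-4, 3e-4, 4e-4))
  b2 <- build_blocks(ss2, select_lead_snps(ss2))
  expect_equal(anyDuplicated(b2$snp_id), 0)
  expect_setequal(b2$snp_id, ss2$snp_id)
  # every shared candidate is within 1 Mb of both leads; the stronger
  # lead (p = 1e-9, pos 1e6) must own them
  owner <- b2$block_id[b2$snp_id == "rs003"]
  lead1_block <- b2$block_id[b2$snp_id == "rs001"]
  expect_equal(owner, lead1_block)

  # members lie within the window of their own lead
  for (bid in unique(b2$block_id)) {
    mem <- b2[b2$block_id == bid, ]
    lead <- mem[mem$is_lead, ]
    expect_true(all(abs(mem$pos - lead$pos) <= 1e6))
  }

  # leads absent from the records are a consistency error
  fake <- make_sumstats("9", 42, 1e-9, snp_id = "ghost")
  expect_error(build_blocks(ss2, fake),
               class = "epifinemap_consistency_error")
})

test_that("block weights follow the tiered step function with strict
           boundaries", {
  expect_equal(assign_block_weight(1e-9), 10)
  expect_equal(assign_block_weight(1e-7), 8)
  expect_equal(assign_block_weight(1e-6), 6)
  expect_equal(assign_block_weight(1e-5), 4)
  expect_equal(assign_block_weight(2e-4), 2)
  # boundaries fall into the weaker tier
  expect_equal(assign_block_weight(c(5e-8, 5e-7, 5e-6, 5e-5)),
               c(8, 6, 4, 2))
  # false cases always get 2
  expect_equal(assign_block_weight(NA, control = TRUE), 2)
  expect_equal(assign_block_weight(c(1e-9, NA), control = c(FALSE, TRUE)),
               c(10, 2))
  # out-of-domain true cases
  expect_error(assign_block_weight(5e-4), class = "epifinemap_domain_error")
  expect_error(assign_block_weight(0), class = "epifinemap_domain_error")

  # nonincreasing step function over (0, 5e-4)
  grid <- 10^seq(log10(1e-10), log10(4.99e-4), length.out = 400)
  w <- assign_block_weight(grid)
  expect_true(all(diff(w) <= 0))  # increasing p -> weight never grows
  expect_setequal(unique(w), c(2, 4, 6, 8, 10))
})

test_that("chromosome split partitions blocks into disjoint roles", {
  ss <- make_sumstats(c(3, 17, 12), c(1e6, 1e6, 1e6), rep(1e-9, 3))
  blocks <- build_blocks(ss, select_lead_snps(ss))
  sp <- split_by_chromosome(blocks)
  expect_equal(sp$train$chrom, "3")
  expect_equal(sp$validation$chrom, "17")
  expect_equal(sp$test$chrom, "12")

  # empty input -> three empty lists
  sp0 <- split_by_chromosome(blocks[0, ])
  expect_true(all(vapply(sp0, nrow, integer(1)) == 0))

  # unassigned chromosome: warn-and-drop by default, error on request
  ssx <- make_sumstats(c("3", "X"), c(1e6, 1e6), c(1e-9, 1e-9))
  bx <- build_blocks(ssx, select_lead_snps(ssx))
  expect_warning(spx <- split_by_chromosome(bx), "X")
  expect_equal(sum(vapply(spx, nrow, integer(1))), 1)
  expect_error(split_by_chromosome(bx, unassigned = "error"), "X")

  expect_error(chromosome_split(train = 1:10, test = 10:14))
})

test_that("block writer/reader round-trips and emits 0-based BED spans", {
  ss <- make_sumstats("1", c(1e6, 1.1e6, 3e6), c(1e-9, 1e-5, 1e-6))
  blocks <- build_blocks(ss, select_lead_snps(ss))
  dir <- withr::local_tempdir()
  paths <- write_blocks(blocks, dir)
  back <- read_blocks(dir)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(blocks),
               ignore_attr = TRUE)
  bed <- readr::read_tsv(paths[["bed"]], col_names = c("chrom", "start",
                                                       "end", "block_id"),
                         col_types = "ciic", progress = FALSE)
  b1 <- blocks[blocks$block_id == bed$block_id[1], ]
  expect_equal(bed$start[1], min(b1$pos) - 1)
  expect_equal(bed$end[1], max(b1$pos))
})
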