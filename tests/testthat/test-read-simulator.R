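test_that("amplicon simulation follows the copy-number x amplifiability weight law", {
  rs <- tiny_refset()
  prof <- generate_profile(rs, lognormal_sigma = 0, seed = 1)

  # single amplifiable taxon: all pairs from it, read = product prefix
  one <- subset_reference_set(rs, rs$taxa$taxon_id[1])
  pone <- structure(setNames(1, one$taxa$taxon_id), class = "CommunityProfile")
  amp <- simulate_amplicon(one, pone, 50, error_model = default_error_model(0),
                           seed = 2)
  expect_equal(nrow(amp), 50L)
  expect_true(all(amp$taxon_id == one$taxa$taxon_id))
  vp <- virtual_pcr_refset(one)
  expect_true(all(amp$fwd_start == vp$product_start))
  expect_true(all(amp$rev_end == vp$product_end))
  # the forward read starts with (a realization of) the forward primer
  codes <- strsplit(one$primers$fwd$seq, NULL)[[1]]
  prefix <- strsplit(substr(amp$fwd_seq[1], 1, length(codes)), NULL)[[1]]
  expect_true(all(iupac_match(prefix, codes)))
  # reads lie within the product interval
  expect_true(all(amp$fwd_start >= vp$product_start & amp$rev_end <= vp$product_end))

  # two taxa, fractions 0.5/0.5, copies 1 and 4 -> taxon-2 share ~ 0.8
  rs2 <- subset_reference_set(rs, rs$taxa$taxon_id[1:2])
  rs2$taxa$copy_number <- c(1L, 4L)
  p2 <- structure(setNames(c(0.5, 0.5), rs2$taxa$taxon_id),
                  class = "CommunityProfile")
  amp2 <- simulate_amplicon(rs2, p2, 20000, error_model = default_error_model(0),
                            seed = 11)
  share2 <- mean(amp2$taxon_id == rs2$taxa$taxon_id[2])
  sd_bin <- sqrt(0.8 * 0.2 / 20000)
  expect_lt(abs(share2 - 0.8), 3 * sd_bin)

  # a taxon failing virtual PCR yields no reads
  lin <- generate_taxonomy(c(1, 2, 2, 2, 2, 4), seed = 11)
  rsb <- generate_reference_set(lin, seed = 12, biased_fraction = 0.25)
  pb <- generate_profile(rsb, lognormal_sigma = 0, seed = 1)
  ampb <- simulate_amplicon(rsb, pb, 2000, seed = 3)
  biased_ids <- rsb$taxa$taxon_id[rsb$taxa$primer_biased]
  expect_equal(sum(biased_ids %in% ampb$taxon_id), 0L)

  # all taxa unamplifiable -> error
  all_biased <- rsb
  all_biased$taxa$copy_number[!rsb$taxa$primer_biased] <- 0L
  expect_error(simulate_amplicon(all_biased, pb, 10, seed = 1), "no amplifiable")
})

test_that("shotgun DNA mixes rRNA and background pairs at the stated rate", {
  rs <- tiny_refset()
  prof <- generate_profile(rs, lognormal_sigma = 0, seed = 1)
  dna <- simulate_shotgun_dna(rs, prof, 20000, rrna_read_fraction = 0.05,
                              seed = 4)
  expect_equal(nrow(dna), 20000L)
  n_r <- sum(dna$taxon_id != "background")
  expect_lt(abs(n_r - 1000), 3 * sqrt(20000 * 0.05 * 0.95))
  # rrna_read_fraction 1 -> no background
  dna1 <- simulate_shotgun_dna(rs, prof, 500, rrna_read_fraction = 1, seed = 5)
  expect_false(any(dna1$taxon_id == "background"))
  # fragment starts cover blocks approximately uniformly
  dna2 <- simulate_shotgun_dna(subset_reference_set(rs, rs$taxa$taxon_id[1]),
                               structure(setNames(1, rs$taxa$taxon_id[1]),
                                         class = "CommunityProfile"),
                               20000, rrna_read_fraction = 1, seed = 6)
  b <- rs$blocks
  bin <- findInterval(dna2$fwd_start, b$start)
  obs <- tabulate(bin, nbins = nrow(b))
  expected <- (b$end - b$start) / max(b$end)
  pval <- suppressWarnings(chisq.test(obs, p = expected)$p.value)
  expect_gt(pval, 0.01)
})

test_that("shotgun RNA weights by expression, not copy number", {
  rs <- tiny_refset()
  rs2 <- subset_reference_set(rs, rs$taxa$taxon_id[1:2])
  p2 <- structure(setNames(c(0.5, 0.5), rs2$taxa$taxon_id),
                  class = "CommunityProfile")
  # equal expression -> shares track cell fractions
  rs2$taxa$expression_rate <- c(1, 1)
  rna_eq <- simulate_shotgun_rna(rs2, p2, 10000, rrna_read_fraction = 1, seed = 7)
  expect_lt(abs(mean(rna_eq$taxon_id == rs2$taxa$taxon_id[1]) - 0.5),
            3 * sqrt(0.25 / 10000))
  # expression 1 vs 20 -> shares ~ (1/21, 20/21)
  rs2$taxa$expression_rate <- c(1, 20)
  rs2$taxa$copy_number <- c(7L, 1L)     # must not matter
  rna <- simulate_shotgun_rna(rs2, p2, 20000, rrna_read_fraction = 1, seed = 8)
  share <- mean(rna$taxon_id == rs2$taxa$taxon_id[2])
  p_exp <- 20 / 21
  expect_lt(abs(share - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("read share regresses on the theoretical weight with high R^2", {
  sc <- default_scenario()
  rs <- sc$refset; prof <- sc$profile_a
  rna <- simulate_shotgun_rna(rs, prof, 100000, rrna_read_fraction = 1, seed = 9)
  w <- as.numeric(prof[rs$taxa$taxon_id]) * rs$taxa$expression_rate
  w <- w / sum(w)
  obs <- as.numeric(table(factor(rna$taxon_id, levels = rs$taxa$taxon_id))) /
    nrow(rna)
  expect_gt(summary(lm(obs ~ w))$r.squared, 0.95)
})

test_that("simulated pairs conserve counts and round-trip through FASTQ", {
  rs <- tiny_refset()
  prof <- generate_profile(rs, seed = 2)
  amp <- simulate_amplicon(rs, prof, 25, seed = 3)
  expect_equal(nrow(amp), 25L)
  expect_true(all(nchar(amp$fwd_seq) == nchar(amp$fwd_qual)))
  expect_true(all(nchar(amp$rev_seq) == nchar(amp$rev_qual)))
  # truth intervals sit inside the template
  lens <- nchar(rs$seqs)[match(amp$taxon_id, rs$taxa$taxon_id)]
  expect_true(all(amp$fwd_start >= 0 & amp$rev_end <= lens))
  prefix <- tempfile("reads")
  write_read_pairs(amp, prefix)
  r1 <- read_fastq(paste0(prefix, "_R1.fastq"))
  expect_equal(nrow(r1), 25L)
  expect_equal(r1$sequence, amp$fwd_seq)
  expect_equal(r1$quality, amp$fwd_qual)
  truth <- read.table(paste0(prefix, "_truth.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(truth), 50L)
  unlink(paste0(prefix, c("_R1.fastq", "_R2.fastq", "_truth.tsv")))
  # determinism
  amp_b <- simulate_amplicon(rs, prof, 25, seed = 3)
  expect_identical(amp, amp_b)
})
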