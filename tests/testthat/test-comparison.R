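cl_of <- function(genus_counts) {
  g <- rep(names(genus_counts), genus_counts)
  data.frame(read_id = sprintf("r%04d", seq_along(g)),
             domain = "d1", phylum = paste0("p_", substr(g, 1, 2)),
             class = "c1", order = "o1", family = "f1", genus = g,
             stringsAsFactors = FALSE)
}

test_that("subsample draws without replacement, deterministically", {
  cl <- cl_of(c(gA = 30, gB = 70))
  expect_identical(subsample(cl, 100, seed = 1), cl)
  expect_equal(nrow(subsample(cl, 0, seed = 1)), 0L)
  s1 <- subsample(cl, 40, seed = 5)
  expect_equal(nrow(s1), 40L)
  expect_identical(s1, subsample(cl, 40, seed = 5))
  expect_false(any(duplicated(s1$read_id)))
  expect_error(subsample(cl, 101, seed = 1), "exceeds")
})

test_that("abundance tables count per rank and track unassigned reads", {
  cl <- cl_of(c(gA = 10))
  tab <- abundance_table(cl, "genus")
  expect_equal(tab$count, 10L)
  expect_equal(tab$fraction, 1)
  # phylum-only assignments land in the unassigned bucket at genus
  cl2 <- cl_of(c(gA = 5, gB = 5))
  cl2$genus[6:10] <- NA
  tab2 <- abundance_table(cl2, "genus")
  expect_equal(attr(tab2, "unassigned"), 5L)
  expect_equal(sum(tab2$count), 5L)
  # truth-mode synthetic run equals the simulator's multinomial counts
  rs <- tiny_refset()
  prof <- generate_profile(rs, seed = 2)
  amp <- simulate_amplicon(rs, prof, 400, error_model = default_error_model(0),
                           seed = 3)
  asn <- truth_assignments(amp, rs)
  tab3 <- abundance_table(asn, "genus")
  direct <- table(rs$taxa$genus[match(amp$taxon_id, rs$taxa$taxon_id)])
  expect_equal(setNames(tab3$count, tab3$taxon),
               setNames(as.integer(direct), names(direct))[tab3$taxon])
})

test_that("log2 ratio tables are antisymmetric with a pseudocount guard", {
  a <- abundance_table(cl_of(c(gA = 100, gB = 100)), "genus")
  b <- abundance_table(cl_of(c(gA = 100, gB = 100)), "genus")
  expect_true(all(log2_ratio_table(a, b)$log2_ratio == 0))
  # a doubled share gives a ratio near 1
  c_tab <- abundance_table(cl_of(c(gA = 200, gB = 200)), "genus")
  half <- abundance_table(cl_of(c(gA = 100, gB = 300)), "genus")
  r <- log2_ratio_table(c_tab, half)
  expect_equal(r$log2_ratio[r$taxon == "gA"], 1, tolerance = 0.02)
  ab <- log2_ratio_table(a, c_tab)
  ba <- log2_ratio_table(c_tab, a)
  expect_equal(ab$log2_ratio, -ba$log2_ratio)
  # a taxon absent from one table keeps a finite ratio
  d <- abundance_table(cl_of(c(gA = 200)), "genus")
  rd <- log2_ratio_table(d, a)
  expect_true(all(is.finite(rd$log2_ratio)))
  ta <- a; attr(ta, "rank") <- "phylum"
  expect_error(log2_ratio_table(ta, a), "same rank")
})

test_that("r_squared matches the closed-form Pearson computation", {
  a <- abundance_table(cl_of(c(gA = 5, gB = 3, gC = 2)), "genus")
  b <- abundance_table(cl_of(c(gA = 4, gB = 4, gC = 2)), "genus")
  # hand evaluation of Pearson r^2 for (.5,.3,.2) vs (.4,.4,.2) = 4/7
  expect_equal(r_squared(a, b), 4 / 7, tolerance = 1e-9)
  # perfect linearity
  b2 <- abundance_table(cl_of(c(gA = 10, gB = 6, gC = 4)), "genus")
  expect_equal(r_squared(a, b2), 1, tolerance = 1e-12)
  # constant vector -> undefined
  u1 <- abundance_table(cl_of(c(gA = 5, gB = 5, gC = 5)), "genus")
  expect_warning(out <- r_squared(u1, a), "zero variance")
  expect_true(is.na(out))
  expect_warning(out2 <- r_squared(abundance_table(cl_of(c(gA = 5)), "genus"), a),
                 "fewer than 3")
  expect_true(is.na(out2))
})

test_that("differential abundance recovers nulls, folds and guards zeros", {
  reps <- function(counts, n = 3, jitter = 0) {
    lapply(seq_len(n), function(i) {
      cc <- setNames(pmax(1, round(counts * (1 + jitter * (i - 2)))),
                     names(counts))
      abundance_table(cl_of(cc), "genus")
    })
  }
  # identical replicate sets: fold 1, p ~ 1
  same <- reps(c(gA = 50, gB = 50))
  da <- differential_abundance(same, same, "genus")
  expect_true(all(da$fold == 1))
  expect_true(all(da$p_value == 1))
  # a strong decrease is recovered with direction
  before <- reps(c(gA = 600, gB = 400), jitter = 0.02)
  after <- reps(c(gA = 100, gB = 900), jitter = 0.02)
  da2 <- differential_abundance(before, after, "genus")
  rowA <- da2[da2$taxon == "gA", ]
  expect_equal(rowA$direction, "decrease")
  expect_gt(rowA$fold, 3)
  expect_lt(rowA$p_value, 0.05)
  # absent-after taxon: finite fold, flagged
  gone <- reps(c(gB = 1000))
  da3 <- differential_abundance(before, gone, "genus")
  rowGone <- da3[da3$taxon == "gA", ]
  expect_true(is.finite(rowGone$fold))
  expect_true(rowGone$absent_flag)
  expect_error(differential_abundance(before[1], after, "genus"), "replicates")
})

test_that("an injected 6-fold depletion is recovered from replicates", {
  sc <- default_scenario()
  rs <- sc$refset
  tabs_for <- function(profile, seed0) lapply(1:3, function(i) {
    amp <- simulate_amplicon(rs, profile, 20000, seed = seed0 + i)
    abundance_table(truth_assignments(amp, rs), "genus")
  })
  da <- differential_abundance(tabs_for(sc$profile_a, 300),
                               tabs_for(sc$profile_b, 310), "genus")
  hit <- da[da$taxon == "g03", ]          # configured 1/6 fold in condition b
  expect_equal(hit$direction, "decrease")
  expect_gt(hit$fold, 4.5)
  expect_lt(hit$fold, 8)
  expect_lt(hit$p_value, 0.05)
})

test_that("mean copy numbers aggregate consistently across ranks", {
  rs <- tiny_refset()
  one <- subset_reference_set(rs, rs$taxa$taxon_id[1])
  one$taxa$copy_number <- 4L
  expect_equal(mean_copy_number_by_taxon(one, "genus")$mean_copy_number, 4)
  two <- subset_reference_set(rs, rs$taxa$taxon_id[1:2])
  two$taxa$copy_number <- c(1L, 7L)
  two$taxa$genus <- "gSame"
  expect_equal(mean_copy_number_by_taxon(two, "genus")$mean_copy_number, 4)
  # phylum mean equals the genus-count-weighted mean of genus means
  sc <- default_scenario()
  g <- mean_copy_number_by_taxon(sc$refset, "genus")
  p <- mean_copy_number_by_taxon(sc$refset, "phylum")
  genus_phylum <- sc$refset$taxa$phylum[match(g$taxon, sc$refset$taxa$genus)]
  manual <- tapply(g$mean_copy_number * g$n_taxa, genus_phylum, sum) /
    tapply(g$n_taxa, genus_phylum, sum)
  expect_equal(p$mean_copy_number, as.numeric(manual[p$taxon]))
})
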