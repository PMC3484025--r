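cfg <- enrichment_config()

test_that("MAF bins are left-closed width-0.05 intervals with a closed top", {
  expect_equal(assign_maf_bin(0.02, cfg), 0L)
  expect_equal(assign_maf_bin(0.05, cfg), 1L)   # boundary starts next bin
  expect_equal(assign_maf_bin(0.50, cfg), 9L)   # top bin closed
  # binary-representation jitter at boundaries must not misbin
  expect_equal(assign_maf_bin(c(0.10, 0.15, 0.30, 0.45), cfg),
               c(2L, 3L, 6L, 9L))
  expect_error(assign_maf_bin(0.51, cfg),
               class = "eqtlenrich_validation_error")
  expect_error(assign_maf_bin(-0.01, cfg),
               class = "eqtlenrich_validation_error")
})

test_that("bin profiles tally per bin and sum to the list size", {
  u <- new_snp_universe(data.frame(
    rsid = c("a", "b", "c"), chrom = "1", pos = 1:3,
    maf = c(0.01, 0.02, 0.30)
  ))
  p <- bin_profile(c("a", "b", "c"), u, cfg)
  expect_equal(sum(p), 3)
  expect_equal(unname(p[1]), 2L)
  expect_equal(unname(p[7]), 1L)   # 0.30 is in the 7th interval (bin 6)
  expect_equal(sum(bin_profile(character(0), u, cfg)), 0)
  expect_error(bin_profile("nope", u, cfg), "nope")
})

test_that("null sets reproduce the observed bin composition exactly", {
  u <- tiny_universe()
  rsids <- c("rs01", "rs02", "rs04", "rs11")  # mafs 0.02/0.30/0.30/0.02
  prof <- bin_profile(rsids, u, cfg)
  sets <- sample_matched_null(u, prof, n_sets = 200, seed = 7)
  expect_length(sets, 200)
  for (s in sets) {
    expect_equal(unname(bin_profile(s, u, cfg)), unname(prof))
    expect_false(anyDuplicated(s) > 0)
  }
})

test_that("a universe that exactly fills the profile forces permutations", {
  u <- new_snp_universe(data.frame(
    rsid = sprintf("r%d", 1:4), chrom = "1", pos = 1:4,
    maf = c(0.02, 0.02, 0.3, 0.3)
  ))
  prof <- bin_profile(u$rsid, u, cfg)
  sets <- sample_matched_null(u, prof, n_sets = 25, seed = 1)
  for (s in sets) expect_setequal(s, u$rsid)

  # all-zero profile: empty sets
  empty <- sample_matched_null(u, bin_profile(character(0), u, cfg),
                               n_sets = 5, seed = 1)
  expect_true(all(lengths(empty) == 0))
})

test_that("infeasible bins are reported with their deficit", {
  u <- tiny_universe()   # 10 SNPs per bin
  prof <- bin_profile(rep(c("rs01", "rs02"), 1), u, cfg)
  prof[1] <- 12L   # demand more bin-0 SNPs than exist
  err <- tryCatch(sample_matched_null(u, prof, 2, seed = 1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "deficit 2")
  expect_error(sample_matched_null(u, prof, 2, seed = 1),
               class = "eqtlenrich_validation_error")
})

test_that("per-SNP inclusion frequency matches the uniform-draw binomial", {
  # 10 bin-0 SNPs, 4 drawn per set: inclusion probability 0.4 each
  u <- new_snp_universe(data.frame(
    rsid = sprintf("r%02d", 1:10), chrom = "1", pos = 1:10, maf = 0.02
  ))
  prof <- bin_profile(u$rsid[1:4], u, cfg)
  sets <- sample_matched_null(u, prof, n_sets = 1000, seed = 99)
  freq <- table(factor(unlist(sets), levels = u$rsid)) / 1000
  se <- sqrt(0.4 * 0.6 / 1000)
  expect_true(all(abs(freq - 0.4) <= 3 * se))
})

test_that("empirical P is the matches-or-exceeds proportion", {
  expect_equal(empirical_p(3, c(0, 1, 2, 3, 4))$p, 0.4)
  z <- empirical_p(6, 1:5)
  expect_equal(z$p, 0)
  expect_equal(z$display, "<0.2")
  expect_equal(empirical_p(0, c(0, 5, 2))$p, 1)
  expect_equal(empirical_p(2, rep(c(1, 2), 500))$display, "0.5")
  expect_error(empirical_p(1, integer(0)),
               class = "eqtlenrich_validation_error")
  # monotone non-increasing in the observed count
  set.seed(42)
  nulls <- rpois(200, 5)
  ps <- vapply(0:15, function(k) empirical_p(k, nulls)$p, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("identical seeds reproduce null draws; different seeds differ", {
  u <- tiny_universe()
  prof <- bin_profile(c("rs01", "rs02", "rs03"), u, cfg)
  s1 <- sample_matched_null(u, prof, 50, seed = 123)
  s2 <- sample_matched_null(u, prof, 50, seed = 123)
  s3 <- sample_matched_null(u, prof, 50, seed = 124)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  rec <- eqtl_rows("rs01", "GA", "1", 1.5e6, 1e-5)
  h <- hits_of(c("rs01", "rs04"))
  r1 <- run_enrichment(h, rec, "parietal", u,
                       enrichment_config(n_null_sets = 100, seed = 5))
  r2 <- run_enrichment(h, rec, "parietal", u,
                       enrichment_config(n_null_sets = 100, seed = 5))
  expect_identical(r1$null_counts, r2$null_counts)
})

test_that("degenerate enrichment inputs behave as defined", {
  u <- tiny_universe()
  h <- hits_of(c("rs01", "rs02"))
  # empty eQTL table: observed 0, all null counts 0, P = 1
  r <- suppressWarnings(run_enrichment(h, eqtl_rows(character(0),
                                                    character(0),
                                                    character(0),
                                                    integer(0),
                                                    numeric(0)),
                                       "parietal", u,
                                       enrichment_config(n_null_sets = 30,
                                                         seed = 2)))
  expect_equal(r$observed_count, 0L)
  expect_true(all(r$null_counts == 0))
  expect_equal(r$empirical_p, 1)

  # saturated universe: every SNP an eQTL, observed = every null count
  rec <- eqtl_rows(u$rsid, paste0("G", seq_len(nrow(u))), u$chrom,
                   pmax(u$pos - 1e5, 1), rep(1e-6, nrow(u)))
  r2 <- run_enrichment(h, rec, "parietal", u,
                       enrichment_config(n_null_sets = 30, seed = 2))
  expect_equal(r2$observed_count, 2L)
  expect_true(all(r2$null_counts == 2))
  expect_equal(r2$empirical_p, 1)
})

test_that("empirical P approaches the exact enumeration tail on a small case", {
  # 20-SNP universe, 5 eQTLs, 4-SNP hit list (the unit-scale oracle case)
  u <- tiny_universe()
  eqtl_snps <- c("rs01", "rs02", "rs11", "rs12", "rs13")
  rec <- eqtl_rows(eqtl_snps, paste0("G", 1:5),
                   u$chrom[match(eqtl_snps, u$rsid)],
                   u$pos[match(eqtl_snps, u$rsid)] + 1e5,
                   rep(1e-6, 5))
  h <- hits_of(c("rs01", "rs02", "rs03", "rs11"))
  res <- run_enrichment(h, rec, "parietal", u,
                        enrichment_config(n_null_sets = 2000, seed = 31))

  bins <- assign_maf_bin(u$maf, cfg)
  prof <- bin_profile(h$rsid, u, cfg)
  need <- stats::setNames(as.integer(prof),
                          as.character(0:(cfg$n_bins - 1)))
  exact <- exact_matched_tail(u$rsid %in% eqtl_snps, bins, need,
                              res$observed_count)
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(res$empirical_p - exact), 3 * mc_se + 1e-12)
})

test_that("planted enrichment drives empirical P down monotonically", {
  # moderate scale chosen so power at theta = 2 is partial, not saturated
  run_theta <- function(theta, seed) {
    cfgs <- sim_config(n_universe = 4000, n_hits = 80,
                       tissues = "parietal", analyses = "a1",
                       enrichment_multiplier = theta, seed = seed)
    b <- simulate_study(cfgs)
    run_enrichment(b$hit_lists[[1]], b$eqtl_map$parietal, "parietal",
                   b$universe,
                   enrichment_config(n_null_sets = 300,
                                     seed = seed + 1))$empirical_p
  }
  meds <- vapply(c(1, 2, 4), function(th) {
    stats::median(vapply(1:30, function(i) run_theta(th, 1000 * th + i),
                         0))
  }, 0)
  expect_gt(meds[1], meds[2])
  expect_gt(meds[2], meds[3])
})
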