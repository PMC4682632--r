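test_that("protection factor is the exponential of the weighted structure terms", {
  # fully disordered coil is unprotected regardless of weights
  expect_equal(protection_factor(0, 1, ngome_weights(2, 5)), 1.0)
  # closed-form oracle: exp(wH*H + wO*(1-D))
  expect_equal(protection_factor(1, 0), exp(0.571 + 2.989))
  expect_equal(protection_factor(0, 0.5), exp(2.989 * 0.5))
  expect_equal(protection_factor(1, 0), 35.16, tolerance = 1e-3)
  expect_equal(protection_factor(0, 0.5), 4.457, tolerance = 1e-3)
  expect_error(protection_factor(0, 1.2), "\\[0, 1\\]")
  expect_error(protection_factor(0.5, 0.5), "H must be")
  expect_error(protection_factor(1, 0, ngome_weights(-1, 1)), "non-negative")
})

test_that("percent deamidation follows base-2 exponential decay", {
  for (x in c(0.5, 1, 10, 1000)) expect_equal(percent_deamidated(x, x), 50)
  expect_equal(percent_deamidated(7, 0), 0)
  expect_equal(percent_deamidated(1, 2), 75)
  expect_error(percent_deamidated(0, 1), "positive")
  expect_error(percent_deamidated(1, -1), "non-negative")
  # strictly increasing in t, strictly decreasing in t50, bounded
  t <- seq(0, 50, by = 0.5)
  p <- percent_deamidated(3, t)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 100))
  expect_true(all(diff(percent_deamidated(c(1, 2, 5, 10), 3)) < 0))
})

test_that("protein half-time composes independent first-order sites harmonically", {
  expect_equal(protein_half_time(9.7), 9.7)
  expect_equal(protein_half_time(c(10, 10)), 5)
  expect_equal(protein_half_time(c(1, 1000)), 1000 / 1001)
  expect_true(is.na(protein_half_time(numeric(0))))
  expect_true(is.na(protein_half_time(NA_real_)))
  expect_equal(protein_half_time(c(4, NA)), 4)  # unusable sites excluded
  expect_error(protein_half_time(c(3, -1)), "positive")
  # never exceeds the fastest site; adding a site never slows the protein
  set.seed(11)
  for (i in 1:20) {
    t50s <- rexp(sample(2:6, 1), rate = 0.1) + 0.1
    expect_lte(protein_half_time(t50s), min(t50s))
    expect_lte(protein_half_time(c(t50s, 5)), protein_half_time(t50s))
  }
})

test_that("protein half-time matches an exponential first-event simulation", {
  t50s <- c(3, 40, 11)
  set.seed(1)
  draws <- replicate(1e5, min(rexp(length(t50s), rate = log(2) / t50s)))
  expect_equal(protein_half_time(t50s), median(draws), tolerance = 0.02)
})

test_that("site classification thresholds with ties called positive", {
  expect_equal(classify_site(1, 10), "positive")
  expect_equal(classify_site(10, 10), "positive")
  expect_equal(classify_site(11, 10), "negative")
  expect_true(is.na(classify_site(NA_real_, 10)))
  expect_error(classify_site(1, 0), "positive number")
})

test_that("site prediction multiplies intrinsic half-time by the protection factor", {
  tab <- toy_table()
  sites <- find_asn_sites("MNGK", "p")
  # unprotected: prediction reduces to the intrinsic half-time
  pred <- predict_sites(sites, uniform_profile(4, H = 0, D = 1), table = tab)
  expect_equal(pred$t50_ngome, 1.0)
  expect_equal(pred$protection, 1.0)
  # helical and fully ordered with the published weights
  pred <- predict_sites(sites, uniform_profile(4, H = 1, D = 0), table = tab)
  expect_equal(pred$t50_ngome, exp(0.571 + 2.989), tolerance = 1e-12)
  expect_equal(pred$t50_ngome, pred$t50_sequence * pred$protection)
  # profile that does not cover the site
  expect_error(predict_sites(sites, uniform_profile(1)), "cover")
})

test_that("predicted half-time responds monotonically to structure", {
  tab <- toy_table()
  sites <- find_asn_sites("MNGK", "p")
  ds <- seq(0, 1, by = 0.1)
  t50_by_d <- vapply(ds, function(d) {
    predict_sites(sites, uniform_profile(4, H = 0, D = d), table = tab)$t50_ngome
  }, numeric(1))
  expect_true(all(diff(t50_by_d) < 0))  # more disorder, faster deamidation
  for (d in c(0, 0.5, 1)) {
    t_coil <- predict_sites(sites, uniform_profile(4, H = 0, D = d), table = tab)$t50_ngome
    t_helix <- predict_sites(sites, uniform_profile(4, H = 1, D = d), table = tab)$t50_ngome
    expect_gte(t_helix, t_coil)
    expect_gte(t_coil, 1.0)  # never faster than the intrinsic half-time
  }
})

test_that("whole-protein prediction composes sites and handles edge cases", {
  tab <- toy_table()
  p <- predict_protein("MANGALAK", uniform_profile(8, H = 0, D = 1),
                       table = tab, protein_id = "x")
  expect_equal(nrow(p$sites), 1L)
  expect_equal(p$t50_protein, 1.0)
  # no internal Asn: NA half-time, zero site rows
  p0 <- predict_protein("MAGK", uniform_profile(4), table = tab)
  expect_equal(nrow(p0$sites), 0L)
  expect_true(is.na(p0$t50_protein))
  # protein half-time never exceeds the fastest site
  fx <- generate_fixture(n_sequences = 5, seed = 3)
  for (id in names(fx$sequences)) {
    pp <- predict_protein(fx$sequences[[id]], fx$profiles[[id]],
                          table = read_halftime_table(), protein_id = id)
    if (nrow(pp$sites)) {
      expect_lte(pp$t50_protein, min(pp$sites$t50_ngome, na.rm = TRUE))
    }
  }
})

test_that("sites with N+1 absent from the table get missing half-times, not dropped", {
  tab <- toy_table()
  p <- predict_protein("MANPANGK", uniform_profile(8, H = 0, D = 1), table = tab)
  expect_equal(p$sites$position, c(3L, 6L))
  expect_true(is.na(p$sites$t50_ngome[1]))   # Asn-Pro: no invented value
  expect_equal(p$sites$t50_ngome[2], 1.0)
  expect_equal(p$t50_protein, 1.0)           # composed over usable sites only
})

test_that("hypothetical scan covers internal positions with wild-type tracks", {
  tab <- toy_table()
  scan <- hypothetical_scan("MAGK", uniform_profile(4, H = 0, D = 1), table = tab)
  expect_equal(scan$position, c(2L, 3L))
  expect_equal(scan$t50_ngome[1], 1.0)   # N+1 would be G
  expect_false(any(scan$position %in% c(1L, 4L)))
  # at a real Asn the scan row equals the real prediction
  prof <- make_profile(c(0, 1, 0, 0, 0), c(0.2, 0.1, 0.9, 0.5, 0.3))
  seqstr <- "MANGK"
  scan <- hypothetical_scan(seqstr, prof, table = tab)
  real <- predict_sites(find_asn_sites(seqstr), prof, table = tab)
  row <- scan[scan$position == 3L, ]
  expect_true(row$is_real_asn)
  expect_equal(row$t50_ngome, real$t50_ngome)
  expect_equal(row$is_sequon, real$is_sequon)
  expect_equal(sum(scan$is_real_asn), 1L)
})
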