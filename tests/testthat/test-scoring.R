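geom <- dna_geometry()

event_at <- function(primary_id, region, strand, base_index, energy) {
  p <- volume_center(geom, region, strand, base_index)
  data.frame(primary_id = primary_id, step = 1, kind = "ionization",
             x_nm = p[1], y_nm = p[2], z_nm = p[3], energy_ev = energy)
}

test_that("the SSB threshold is inclusive at 17.5 eV", {
  rules <- scoring_rules()
  hit <- score_ssbs(event_at(1, "backbone", 0, 5, 17.5), geom, rules)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, 0L)
  expect_equal(hit$base_index, 5L)
  miss <- score_ssbs(event_at(1, "backbone", 0, 5, 17.4), geom, rules)
  expect_equal(nrow(miss), 0L)
  # base-region depositions never create breaks
  base_hit <- score_ssbs(event_at(1, "base", 0, 5, 100), geom, rules)
  expect_equal(nrow(base_hit), 0L)
})

test_that("energy accumulates per backbone volume per primary", {
  rules <- scoring_rules()
  same <- rbind(event_at(1, "backbone", 0, 5, 10),
                event_at(1, "backbone", 0, 5, 10))
  expect_equal(nrow(score_ssbs(same, geom, rules)), 1L)
  different <- rbind(event_at(1, "backbone", 0, 5, 10),
                     event_at(1, "backbone", 0, 6, 10))
  expect_equal(nrow(score_ssbs(different, geom, rules)), 0L)
  # separate primaries do not pool energy
  two_prim <- rbind(event_at(1, "backbone", 0, 5, 10),
                    event_at(2, "backbone", 0, 5, 10))
  expect_equal(nrow(score_ssbs(two_prim, geom, rules)), 0L)
  # per-event mode requires each single deposition to pass the threshold
  pe_rules <- scoring_rules(accumulation = "per_event")
  expect_equal(nrow(score_ssbs(same, geom, pe_rules)), 0L)
  expect_equal(nrow(score_ssbs(event_at(1, "backbone", 1, 7, 20), geom,
                               pe_rules)), 1L)
})

test_that("the DSB base-separation rule is inclusive at 10 bases", {
  rules <- scoring_rules()
  mk <- function(b0, b1) rbind(event_at(1, "backbone", 0, b0, 20),
                               event_at(1, "backbone", 1, b1, 20))
  br10 <- score_ssbs(mk(10, 20), geom, rules)
  expect_equal(sum(score_dsbs(br10, rules)$dsb_count), 1L)
  br11 <- score_ssbs(mk(10, 21), geom, rules)
  expect_equal(sum(score_dsbs(br11, rules)$dsb_count), 0L)
  # same-strand pairs never form a DSB under the default rule
  same_strand <- score_ssbs(rbind(event_at(1, "backbone", 0, 10, 20),
                                  event_at(1, "backbone", 0, 12, 20)),
                            geom, rules)
  expect_equal(sum(score_dsbs(same_strand, rules)$dsb_count), 0L)
  # but can under the relaxed flag
  relaxed <- scoring_rules(dsb_requires_opposite_strands = FALSE)
  expect_equal(sum(score_dsbs(same_strand, relaxed)$dsb_count), 1L)
  # zero separation allows only equal base indices
  zero <- scoring_rules(dsb_max_base_separation = 0)
  expect_equal(sum(score_dsbs(br10, zero)$dsb_count), 0L)
  br_eq <- score_ssbs(mk(15, 15), geom, rules)
  expect_equal(sum(score_dsbs(br_eq, zero)$dsb_count), 1L)
})

test_that("greedy DSB pairing equals exhaustive maximum matching", {
  rules <- scoring_rules()
  set.seed(123)
  mismatches <- 0L
  for (i in 1:2000) {
    n <- sample(0:12, 1)
    strand <- sample(0:1, n, replace = TRUE)
    base <- sample(0:40, n, replace = TRUE)
    br <- data.frame(primary_id = rep(1, n), strand = strand,
                     base_index = base, accumulated_energy = rep(20, n))
    greedy <- sum(score_dsbs(br, rules)$dsb_count)
    opt <- oracle_max_dsbs(strand, base, 10, TRUE)
    if (greedy != opt) mismatches <- mismatches + 1L
    expect_equal(greedy, opt)
  }
  expect_equal(mismatches, 0L)
})

test_that("full scoring pipeline equals the naive oracle on random streams", {
  rules <- scoring_rules()
  for (s in 1:20) {
    ev <- make_event_stream(geom, n_primaries = 40, events_per_primary = 4,
                            energy_mean_ev = 25, seed = s)
    br <- score_ssbs(ev, geom, rules)
    or <- oracle_score_ssbs(ev, geom, 17.5)
    expect_equal(nrow(br), nrow(or))
    if (nrow(br)) {
      expect_equal(br$strand, or$strand)
      expect_equal(br$base_index, or$base_index)
      expect_equal(br$accumulated_energy, or$accumulated_energy)
    }
  }
})

test_that("raising the SSB threshold is monotone non-increasing in damage", {
  ev <- make_event_stream(geom, n_primaries = 200, events_per_primary = 5,
                          energy_mean_ev = 30, seed = 99)
  thresholds <- c(5, 10, 17.5, 25, 40)
  counts <- vapply(thresholds, function(th) {
    r <- scoring_rules(ssb_threshold_ev = th)
    br <- score_ssbs(ev, geom, r)
    c(nrow(br), sum(score_dsbs(br, r)$dsb_count))
  }, numeric(2))
  expect_true(all(diff(counts[1, ]) <= 0))
  expect_true(all(diff(counts[2, ]) <= 0))
})

test_that("DSB count never exceeds floor(SSB count / 2)", {
  rules <- scoring_rules()
  set.seed(77)
  for (i in 1:200) {
    n <- sample(0:10, 1)
    br <- data.frame(primary_id = rep(1, n), strand = sample(0:1, n, TRUE),
                     base_index = sample(0:30, n, TRUE),
                     accumulated_energy = rep(20, n))
    expect_lte(sum(score_dsbs(br, rules)$dsb_count), floor(n / 2))
  }
})

test_that("campaign summaries scale counts to frequencies per million", {
  # 7 SSBs in 1e4 primaries -> 700 per 1e6 (scaling arithmetic through the
  # public summary; constructed via a fake campaign object)
  ev <- do.call(rbind, lapply(1:7, function(i)
    event_at(i, "backbone", i %% 2, i, 20)))
  camp <- structure(list(list(species = "electron", energy_ev = 400,
                              seed = 1, n_primaries = 10000L, events = ev,
                              let = 10)),
                    class = "track_campaign")
  s <- score_campaign(camp, geom)
  expect_equal(s$ssb_count, 7)
  expect_equal(s$ssb_per_1e6, 700)
  expect_equal(s$dsb_per_1e6, 0)
  # zero events give an all-zero summary
  camp0 <- structure(list(list(species = "electron", energy_ev = 400,
                               seed = 1, n_primaries = 100L,
                               events = ev[0, ], let = NA_real_)),
                     class = "track_campaign")
  s0 <- score_campaign(camp0, geom)
  expect_equal(s0$ssb_count, 0)
  expect_equal(s0$dsb_count, 0)
})

test_that("aggregation reports mean and max-min spread across seeds", {
  s <- structure(data.frame(species = "electron", energy_ev = 400,
                            seed = 1:2, n_primaries = 100,
                            ssb_count = c(10, 14), dsb_count = c(1, 3),
                            ssb_per_1e6 = c(1e5, 1.4e5),
                            dsb_per_1e6 = c(1e4, 3e4),
                            let_kev_um = c(20, 22)),
                 class = c("damage_summary", "data.frame"))
  a <- aggregate_damage(s)
  expect_equal(a$ssb_per_1e6, 1.2e5)
  expect_equal(a$ssb_spread, 0.4e5)
  expect_equal(a$dsb_per_1e6, 2e4)
  expect_equal(a$let_spread, 2)
  # pooling two equal-n seeds equals the mean of the two frequencies
  expect_equal(a$ssb_per_1e6, sum(s$ssb_count) * 1e6 / sum(s$n_primaries))
})

test_that("relative differences match hand-computed trapezoid arithmetic", {
  a <- data.frame(energy_ev = c(250, 500, 750), ssb_per_1e6 = c(4, 2, 1))
  b <- data.frame(energy_ev = c(250, 500, 750), ssb_per_1e6 = c(2, 1, 0.5))
  rd <- relative_difference(a, b)
  expect_equal(rd$per_energy$pct_diff, c(100, 100, 100))
  expect_equal(rd$integral_pct, 100)
  # identical summaries differ by 0%
  rd0 <- relative_difference(a, a)
  expect_equal(rd0$per_energy$pct_diff, c(0, 0, 0))
  expect_equal(rd0$integral_pct, 0)
  # hand-computed asymmetric case: trapezoid integrals 250*(3+1.5)=1125
  # and 250*(1.5+0.75)=562.5 for b -> +100%; perturb one node
  a2 <- a; a2$ssb_per_1e6 <- c(4, 2, 2)
  ia2 <- 250 * (3 + 2)  # trapezoid of (4,2,2)
  ib <- 250 * (1.5 + 0.75)
  rd2 <- relative_difference(a2, b)
  expect_equal(rd2$integral_pct, 100 * (ia2 - ib) / ib)
  # zero denominator flags NA at that energy
  b0 <- b; b0$ssb_per_1e6[3] <- 0
  expect_true(is.na(relative_difference(a, b0)$per_energy$pct_diff[3]))
  expect_error(relative_difference(a, b[1:2, ]), "grids")
})
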