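test_that("generators are deterministic in (parameters, seed)", {
  a <- gen_binding_traces(1e7, 10, noise = noise_spec(0.002, 1))
  b <- gen_binding_traces(1e7, 10, noise = noise_spec(0.002, 1))
  c <- gen_binding_traces(1e7, 10, noise = noise_spec(0.002, 2))
  expect_identical(a, b)
  expect_false(identical(a[[1]]$signal, c[[1]]$signal))
  s1 <- gen_swv(-0.056, noise = noise_spec(0.01, 5))
  s2 <- gen_swv(-0.056, noise = noise_spec(0.01, 5))
  s3 <- gen_swv(-0.056, noise = noise_spec(0.01, 6))
  expect_identical(s1, s2)
  expect_false(identical(s1$net_current, s3$net_current))
})

test_that("binding traces follow the pseudo-first-order closed form", {
  k_on <- 1.16e7; k_off <- 13.9
  tr <- gen_binding_traces(k_on, k_off, o2_concs = 10e-6,
                           noise = noise_spec(0, NULL))[[1]]
  k_obs <- k_on * 10e-6 + k_off
  a_inf <- 0.18; a0 <- 0.05
  expect_equal(tr$signal, a_inf - (a_inf - a0) * exp(-k_obs * tr$time))
  # >= 99% complete at 68 ms after mixing
  frac <- 1 - exp(-k_obs * 0.068)
  expect_gte(frac, 0.99)
  expect_gte(min(tr$time), 6.8e-4)   # dead time honoured
  # degenerate slope-0 case: k_on = 0 gives identical k_obs everywhere
  trs <- gen_binding_traces(0, 25, o2_concs = c(5, 10, 20) * 1e-6,
                            t_grid = seq(6.8e-4, 0.3, length.out = 100),
                            noise = noise_spec(0, NULL))
  sigs <- sapply(trs, function(x) x$signal)
  expect_equal(sigs[, 1], sigs[, 2])
  expect_equal(sigs[, 1], sigs[, 3])
  expect_error(gen_binding_traces(1e7, 10, o2_concs = -1e-6), "positive")
  expect_error(gen_binding_traces(1e7, 10, t_grid = numeric(0)), "empty")
})

test_that("hemin-loss generator reproduces half-life and rate ordering", {
  tr0 <- gen_hemin_loss_trace(0, noise = noise_spec(0, NULL))
  expect_equal(tr0$signal, rep(0.5, length(tr0$time)))  # offset + amplitude
  k <- 0.22
  tr <- gen_hemin_loss_trace(k, noise = noise_spec(0, NULL))
  t_half <- log(2) / k   # ~3.15 h
  expect_equal(tr$signal, 0.1 + 0.4 * exp(-k * tr$time))  # exact closed form
  decayed <- stats::approx(tr$time, tr$signal, xout = t_half)$y
  expect_equal(decayed, 0.1 + 0.4 / 2, tolerance = 1e-4)   # ~3.15 h half-life
  fast <- gen_hemin_loss_trace(1.86, noise = noise_spec(0, NULL))
  slow <- gen_hemin_loss_trace(1.44, noise = noise_spec(0, NULL))
  expect_true(all(fast$signal[-1] < slow$signal[-1]))
  expect_error(gen_hemin_loss_trace(0.2, amplitude = -1), "amplitude")
})

test_that("autoxidation series hits its closed-form checkpoints", {
  b <- mb_basis()
  ser <- gen_autoxidation_series(1.96, c(0, log(2) / 1.96, 2),
                                 noise = noise_spec(0, NULL))
  expect_equal(ser$absorbance[, 1], b$epsilon[, "oxy"] * 0.01,
               ignore_attr = TRUE)
  expect_equal(ser$f_met_true[2], 0.5)
  const <- gen_autoxidation_series(0, c(0, 1, 2), noise = noise_spec(0, NULL))
  expect_equal(const$absorbance[, 1], const$absorbance[, 3])
  bad <- mb_basis()
  colnames(bad$epsilon) <- c("deoxy", "oxy", "ferryl")
  expect_error(gen_autoxidation_series(1, basis = bad), "met")
})

test_that("redox titration follows the Nernst fraction", {
  E0 <- 0.040
  s <- 8.314462618 * 298.15 / 96485.33212 * log(10)
  tit <- gen_redox_titration(E0, potentials = c(E0 - 0.2, E0 - s, E0,
                                                E0 + s, E0 + 0.2),
                             noise = noise_spec(0, NULL))
  b <- mb_basis()
  mix <- function(f) (b$epsilon[, "deoxy"] * f + b$epsilon[, "met"] * (1 - f)) * 0.01
  expect_equal(tit$absorbance[, 3], mix(0.5), ignore_attr = TRUE)
  # one decade per 59.16 mV for n = 1: [ox]/[red] = 10, so f_red = 1/11
  expect_equal(tit$absorbance[, 4], mix(1 / 11), ignore_attr = TRUE)
  far <- gen_redox_titration(E0, potentials = E0 + seq(0.5, 0.9, 0.1),
                             noise = noise_spec(0, NULL))
  for (j in seq_along(far$potentials)) {
    expect_equal(far$absorbance[, j], b$epsilon[, "met"] * 0.01,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(gen_redox_titration(0.04, potentials = 0.04), ">= 2")
})

test_that("SWV generator peaks at E_peak and converts references", {
  vg <- gen_swv(-0.297, width = 0.04, baseline = c(0, 0),
                noise = noise_spec(0, NULL), reference = "SCE")
  expect_equal(vg$potential[which.max(vg$net_current)], -0.297,
               tolerance = 1e-9)
  expect_equal(convert_reference(-0.297, "SCE", "SHE"), -0.0558)
  expect_error(gen_swv(0, width = 0), "width")
})

test_that("FTIR map generator plants the stated composition contrasts", {
  map <- gen_ftir_map(nx = 6, ny = 6, noise = noise_spec(0.002, 21))
  # inclusion pixels get higher carbonyl weight by default
  expect_gt(map$composition$inclusion[["carbonyl"]],
            map$composition$surround[["carbonyl"]])
  # no beta-sheet weight -> no 1627 feature above noise
  map0 <- gen_ftir_map(nx = 4, ny = 4,
                       composition = list(
                         inclusion = c(protein = 1, lipid = 0.5),
                         surround = c(protein = 1, lipid = 0.5)),
                       noise = noise_spec(0, NULL))
  sp <- ftir_spectrum(map0$wavenumber, map0$spectra[1, ])
  d2 <- second_derivative(sp)
  # amide I (1654) has a strong minimum; 1627 has no resolvable local dip
  expect_true(band_amplitude(d2, 1654)$found)
  expect_false(band_amplitude(d2, 1627)$found)
  # beta-sheet-containing pixel resolves the 1627 shoulder
  mapb <- gen_ftir_map(nx = 4, ny = 4,
                       composition = list(
                         inclusion = c(protein = 1, beta_sheet = 0.8),
                         surround = c(protein = 1, beta_sheet = 0.8)),
                       noise = noise_spec(0, NULL))
  d2b <- second_derivative(ftir_spectrum(mapb$wavenumber, mapb$spectra[1, ]))
  expect_true(band_amplitude(d2b, 1627)$found)
  # pure protein pixel: amide I amplitude > lipid CH2 amplitude
  mapp <- gen_ftir_map(nx = 4, ny = 4,
                       composition = list(
                         inclusion = c(protein = 1),
                         surround = c(protein = 1)),
                       noise = noise_spec(0, NULL))
  spp <- ftir_spectrum(mapp$wavenumber, mapp$spectra[1, ])
  dd <- second_derivative(spp)
  expect_gt(band_amplitude(dd, 1654)$amplitude,
            band_amplitude(dd, 2925)$amplitude)
  expect_error(gen_ftir_map(composition = list(inclusion = c(dna = 1),
                                               surround = c(protein = 1))),
               "unknown band")
})

test_that("expression generator plants exactly the requested promoters", {
  ids <- sprintf("p%04d", c(3, 17, 42, 99, 150))
  m <- gen_expression_matrix(n_promoters = 200, n_samples = 60,
                             enriched_ids = ids, fold = 1e4, seed = 11)
  sc <- enrichment_score(m)
  hits <- sc$promoter[sc$score > 3]
  expect_setequal(hits, ids)
  flat <- gen_expression_matrix(n_promoters = 50, n_samples = 30,
                                enriched_ids = character(), fold = 1, seed = 3)
  sc0 <- enrichment_score(flat)
  expect_lt(max(abs(sc0$score)), 1)   # no planted promoter scores high
  expect_error(gen_expression_matrix(n_promoters = 10,
                                     enriched_ids = "p9999"), "subset")
})

test_that("pedigree genotype simulation couples marker and disease", {
  ped <- ped_nuclear(n_kids = 8, aff = rep(NA, 10))
  mdl <- disease_model(disease_freq = 0.3, penetrance = c(0, 1, 1))
  # theta = 0: affected children always carry a disease-coupled haplotype
  g0 <- gen_pedigree_genotypes(ped, theta_true = 0, model = mdl, seed = 5)
  d <- attr(g0, "disease_genotypes")
  expect_true(all(g0$affected == as.integer(d > 0)))
  # theta = 0.5: marker transmission independent of disease; check by
  # correlation over many simulated sibships
  n_assoc <- function(theta, seed) {
    gg <- gen_pedigree_genotypes(ped, marker_freqs = c(0.5, 0.5),
                                 theta_true = theta,
                                 model = mdl, seed = seed)
    geno <- attr(gg, "genotypes")
    kid <- 3:10
    suppressWarnings(
      stats::cor(rowSums(geno[kid, , drop = FALSE] == 1), gg$affected[kid]))
  }
  cors <- vapply(1:40, function(s) n_assoc(0.5, s), numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.15)
  expect_error(gen_pedigree_genotypes(ped, theta_true = 0.7), "theta_true")
})
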