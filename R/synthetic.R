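# Seeded synthetic-data generators. Every pipeline stage has a generator
# producing its input with known ground truth, so estimators are validated
# by parameter recovery. All generators are pure functions of
# (parameters, seed).

#' Ground-truth parameter set
#'
#' Convenience container for the true parameter values behind a synthetic
#' characterization run.
#'
#' @param k_on M^-1 s^-1; @param k_off s^-1; @param k_minus_H h^-1;
#' @param k_ox min^-1; @param E0 V vs SHE; @param n_electrons integer >= 1;
#' @param enriched_gene_ids character vector; @param theta_true in `[0, 0.5]`.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(k_on = 1.16e7, k_off = 13.92, k_minus_H = 0.22,
                         k_ox = 1.96, E0 = 0.040, n_electrons = 1,
                         enriched_gene_ids = character(), theta_true = 0) {
  for (nm in c("k_on", "k_off", "k_minus_H", "k_ox")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(theta_true, "theta_true", lower = 0, upper = 0.5)
  check_number(n_electrons, "n_electrons", lower = 1)
  structure(list(k_on = k_on, k_off = k_off, k_minus_H = k_minus_H,
                 k_ox = k_ox, E0 = E0, n_electrons = n_electrons,
                 enriched_gene_ids = enriched_gene_ids,
                 theta_true = theta_true), class = "ground_truth")
}

# Stopped-flow dead time (s): fastest time of mixing of the instrument.
SF_DEAD_TIME <- 6.8e-4

#' Simulate stopped-flow O2-binding traces
#'
#' Pseudo-first-order binding monitored at 418 nm:
#' `A(t) = A_inf - (A_inf - A_0) * exp(-k_obs t)` with
#' `k_obs = k_on * conc + k_off`. Time grids start at the 0.68 ms dead time.
#'
#' @param k_on Association rate (M^-1 s^-1). @param k_off Dissociation rate
#'   (s^-1). @param o2_concs O2 concentrations (M), all > 0; default panel
#'   2.5-40 uM. @param t_grid Time grid (s); `NULL` builds a per-trace grid
#'   from the dead time to ~7 relaxation times. @param noise A
#'   [noise_spec()]. @param A0,A_inf Start/end absorbance (AU).
#' @return List of [kinetic_trace()], one per concentration, each carrying
#'   the true concentration in its metadata.
#' @export
gen_binding_traces <- function(k_on, k_off,
                               o2_concs = c(2.5, 5, 10, 20, 30, 40) * 1e-6,
                               t_grid = NULL, noise = noise_spec(),
                               A0 = 0.05, A_inf = 0.18) {
  check_number(k_on, "k_on", lower = 0)
  check_number(k_off, "k_off", lower = 0)
  if (length(o2_concs) == 0L) stop_input("empty concentration list")
  if (any(o2_concs <= 0)) stop_input("concentrations must be positive")
  if (!is.null(t_grid) && length(t_grid) == 0L) stop_input("empty time grid")
  noise <- as_noise_spec(noise)
  with_seed(noise$seed, {
    lapply(seq_along(o2_concs), function(i) {
      conc <- o2_concs[i]
      k_obs <- k_on * conc + k_off
      tg <- if (is.null(t_grid)) {
        seq(SF_DEAD_TIME, SF_DEAD_TIME + 7 / max(k_obs, 1e-9), length.out = 400)
      } else t_grid
      a <- A_inf - (A_inf - A0) * exp(-k_obs * tg)
      if (noise$sigma_abs > 0) a <- a + stats::rnorm(length(a), 0, noise$sigma_abs)
      kinetic_trace(tg, a, unit = "s", wavelength_nm = 418,
                    temperature_C = 25, ligand_conc = conc)
    })
  })
}

#' Simulate a hemin-loss decay at 410 nm
#'
#' `A(t) = offset + amplitude * exp(-k t)` sampled on a 0-350 min grid
#' (stored in hours, matching the h^-1 rate convention).
#'
#' @param k_minus_H Hemin dissociation rate (h^-1), >= 0.
#' @param t_grid_min Sampling times in minutes.
#' @param amplitude,offset Decay amplitude and final absorbance (AU);
#'   requesting a decay with negative amplitude is rejected.
#' @param noise A [noise_spec()].
#' @return A [kinetic_trace()] in hours at 410 nm, 37 C.
#' @export
gen_hemin_loss_trace <- function(k_minus_H, t_grid_min = seq(0, 350, by = 2),
                                 amplitude = 0.4, offset = 0.1,
                                 noise = noise_spec()) {
  check_number(k_minus_H, "k_minus_H", lower = 0)
  if (amplitude < 0) stop_input("negative amplitude for a decay trace")
  t_h <- t_grid_min / 60
  a <- offset + amplitude * exp(-k_minus_H * t_h)
  a <- add_noise(a, noise)
  kinetic_trace(t_h, a, unit = "h", wavelength_nm = 410, temperature_C = 37)
}

#' Simulate an oxy-to-met autoxidation spectral series
#'
#' First-order conversion: `f_met(t) = 1 - exp(-k_ox t)`; each spectrum is a
#' Beer-Lambert mix of the oxy and met basis spectra.
#'
#' @param k_ox Autoxidation rate (min^-1), >= 0.
#' @param t_grid_min Times (min).
#' @param basis An [mb_basis()] (must contain oxy and met states).
#' @param noise A [noise_spec()].
#' @param concentration Overall scale applied to every spectrum.
#' @return A `spectrum_series`: list with `times`, `wavelengths`,
#'   `absorbance` (wavelengths x times) and `f_met_true`.
#' @export
gen_autoxidation_series <- function(k_ox, t_grid_min = seq(0, 120, by = 4),
                                    basis = mb_basis(), noise = noise_spec(),
                                    concentration = 0.01) {
  check_number(k_ox, "k_ox", lower = 0)
  if (!all(c("oxy", "met") %in% colnames(basis$epsilon))) {
    stop_input("basis must contain oxy and met state spectra")
  }
  f_met <- 1 - exp(-k_ox * t_grid_min)
  A <- sapply(f_met, function(f) {
    (basis$epsilon[, "oxy"] * (1 - f) + basis$epsilon[, "met"] * f) *
      concentration
  })
  A <- add_noise(A, noise)
  structure(list(times = t_grid_min, wavelengths = basis$wavelengths,
                 absorbance = A, f_met_true = f_met),
            class = "spectrum_series")
}

# Nernst slope RT ln10 / F in volts at a given temperature.
nernst_slope <- function(temperature_C = 25) {
  (8.314462618 * (273.15 + temperature_C) / 96485.33212) * log(10)
}

#' Simulate a spectroelectrochemical (OTTLE) redox titration
#'
#' Fraction reduced follows the one-(or n-)electron Nernst equation
#' `f(E) = 1 / (1 + 10^((E - E0) n / s))` with `s = RT ln10 / F`; spectra
#' are f-weighted mixes of the reduced (deoxy) and oxidized (met) basis.
#'
#' @param E0 Midpoint potential (V, in `reference` scale).
#' @param n_electrons Electrons transferred (>= 1).
#' @param potentials Applied potentials (V); >= 5 required.
#' @param basis An [mb_basis()]. @param noise A [noise_spec()].
#' @param reference Reference electrode name (see [convert_reference()]).
#' @param temperature_C Cell temperature. @param concentration Scale.
#' @return A `redox_titration` (see [redox_titration()]).
#' @export
gen_redox_titration <- function(E0, n_electrons = 1,
                                potentials = E0 + seq(-0.12, 0.12, by = 0.02),
                                basis = mb_basis(), noise = noise_spec(),
                                reference = "SHE", temperature_C = 25,
                                concentration = 0.01) {
  check_number(E0, "E0")
  check_number(n_electrons, "n_electrons", lower = 1)
  if (length(potentials) < 2L) stop_input("need >= 2 potentials")
  if (length(potentials) < 5L) {
    warning("fewer than 5 potentials; Nernst plots should have >= 5 points",
            call. = FALSE)
  }
  s <- nernst_slope(temperature_C)
  f_red <- 1 / (1 + 10^((potentials - E0) * n_electrons / s))
  A <- sapply(f_red, function(f) {
    (basis$epsilon[, "deoxy"] * f + basis$epsilon[, "met"] * (1 - f)) *
      concentration
  })
  A <- add_noise(A, noise)
  redox_titration(potentials, basis$wavelengths, A, reference = reference,
                  temperature_C = temperature_C)
}

#' Simulate a square-wave voltammogram
#'
#' Gaussian net-current peak on a linear baseline.
#'
#' @param E_peak Peak potential (V, in `reference` scale).
#' @param width Gaussian standard deviation (V), > 0.
#' @param potentials Scan grid (V), strictly monotone.
#' @param baseline `c(intercept, slope)` of the linear baseline (current
#'   units, units/V). @param height Peak height. @param noise [noise_spec()].
#' @param reference Reference electrode name.
#' @return A `voltammogram`: list with `potential`, `net_current`,
#'   `reference`.
#' @export
gen_swv <- function(E_peak, width = 0.04,
                    potentials = seq(E_peak - 0.25, E_peak + 0.25, by = 0.002),
                    baseline = c(0, 0), height = 1, noise = noise_spec(),
                    reference = "SHE") {
  check_number(E_peak, "E_peak")
  if (width <= 0) stop_input("width must be > 0")
  if (any(diff(potentials) == 0) ||
      !(all(diff(potentials) > 0) || all(diff(potentials) < 0))) {
    stop_input("potentials must be strictly monotone")
  }
  i <- baseline[1] + baseline[2] * potentials +
    height * exp(-0.5 * ((potentials - E_peak) / width)^2)
  i <- add_noise(i, noise)
  structure(list(potential = potentials, net_current = i,
                 reference = reference), class = "voltammogram")
}

# ---- FTIR map generation ----------------------------------------------------

#' Default infrared band table for muscle tissue components
#'
#' Centers (cm^-1) and widths for the components used by [gen_ftir_map()]:
#' lipid CH2 stretches (2925/2855), ester/acid carbonyl (1739), protein amide
#' I (1654) and amide II (1545), and intermolecular beta-sheet (1627).
#'
#' @return data.frame with `component`, `center`, `width`, `amp`.
#' @export
ftir_band_table <- function() {
  data.frame(
    component = c("lipid", "lipid", "carbonyl", "protein", "protein", "beta_sheet"),
    center    = c(2925, 2855, 1739, 1654, 1545, 1627),
    width     = c(15, 15, 10, 14, 14, 8),
    amp       = c(1, 0.6, 1, 1, 0.55, 1)
  )
}

#' Simulate an FTIR microspectroscopy map
#'
#' Each pixel spectrum is a sum of Gaussian bands scaled by the composition
#' weights of its region (inclusion / surround / background), on a uniform
#' 900-4000 cm^-1 axis, plus iid Gaussian noise.
#'
#' @param nx,ny Grid size (pixels). @param inclusion_frac Fraction of pixels
#'   labelled `inclusion` (a central block).
#' @param composition Named list: region -> named weights over components in
#'   `band_table` (`lipid`, `carbonyl`, `protein`, `beta_sheet`). Unknown
#'   component names are rejected.
#' @param band_table See [ftir_band_table()].
#' @param wavenumber Uniform ascending axis (cm^-1), default 900-4000 at
#'   1 cm^-1 sampling (instruments sample finer than their optical
#'   resolution; a 15-point filter then spans 15 cm^-1).
#' @param noise A [noise_spec()].
#' @return An `ftir_map`: list with `wavenumber`, `spectra` (pixels x
#'   wavenumbers), `region` (factor), `x_um`, `y_um`, `composition`.
#' @export
gen_ftir_map <- function(nx = 8, ny = 8, inclusion_frac = 0.25,
                         composition = list(
                           inclusion = c(lipid = 1.0, carbonyl = 0.9,
                                         protein = 1.0, beta_sheet = 0.8),
                           surround  = c(lipid = 0.8, carbonyl = 0.25,
                                         protein = 1.2, beta_sheet = 0.0)),
                         band_table = ftir_band_table(),
                         wavenumber = seq(900, 4000, by = 1),
                         noise = noise_spec()) {
  comps <- unique(band_table$component)
  for (reg in names(composition)) {
    bad <- setdiff(names(composition[[reg]]), comps)
    if (length(bad)) {
      stop_input("unknown band component(s) in region '%s': %s", reg,
                 paste(bad, collapse = ", "))
    }
  }
  n_px <- nx * ny
  n_inc <- max(1L, round(n_px * inclusion_frac))
  region <- factor(c(rep("inclusion", n_inc), rep("surround", n_px - n_inc)),
                   levels = c("inclusion", "surround", "background"))
  pure <- sapply(comps, function(cp) {
    b <- band_table[band_table$component == cp, ]
    gaussian_sum(wavenumber, b)
  })
  noise <- as_noise_spec(noise)
  spectra <- with_seed(noise$seed, {
    t(sapply(seq_len(n_px), function(i) {
      w <- composition[[as.character(region[i])]]
      s <- drop(pure[, names(w), drop = FALSE] %*% unname(w))
      if (noise$sigma_abs > 0) s <- s + stats::rnorm(length(s), 0, noise$sigma_abs)
      s
    }))
  })
  xy <- expand.grid(x_um = seq_len(nx) * 10, y_um = seq_len(ny) * 10)
  structure(list(wavenumber = wavenumber, spectra = spectra, region = region,
                 x_um = xy$x_um, y_um = xy$y_um, composition = composition),
            class = "ftir_map")
}

# ---- expression & pedigree generation ---------------------------------------

#' Simulate a promoter-level expression matrix with planted enrichment
#'
#' Log-normal background expression; promoters in `enriched_ids` are
#' multiplied by `fold` in the target-group samples only.
#'
#' @param n_promoters,n_samples Matrix dimensions.
#' @param group_labels Character vector of length `n_samples`; the target
#'   tissue group is named by `target_group`.
#' @param target_group Label of the enriched tissue (default
#'   `"skeletal_muscle"`).
#' @param enriched_ids Promoter ids (subset of rownames) to plant.
#' @param fold Multiplicative enrichment in target samples.
#' @param meanlog,sdlog Log-normal background parameters.
#' @param seed RNG seed.
#' @return An `expression_matrix`: list with `values` (promoters x samples),
#'   `groups`, `enriched_ids`.
#' @export
gen_expression_matrix <- function(n_promoters = 200, n_samples = 60,
                                  group_labels = NULL,
                                  target_group = "skeletal_muscle",
                                  enriched_ids = character(), fold = 1e4,
                                  meanlog = 1, sdlog = 0.5, seed = NULL) {
  if (is.null(group_labels)) {
    n_t <- max(2L, round(n_samples * 0.1))
    group_labels <- c(rep(target_group, n_t), rep("other", n_samples - n_t))
  }
  if (length(group_labels) != n_samples) {
    stop_input("group_labels length must equal n_samples")
  }
  ids <- sprintf("p%04d", seq_len(n_promoters))
  if (!all(enriched_ids %in% ids)) {
    stop_input("enriched_ids must be a subset of the promoter ids (p0001...)")
  }
  vals <- with_seed(seed, {
    m <- matrix(stats::rlnorm(n_promoters * n_samples, meanlog, sdlog),
                n_promoters, n_samples, dimnames = list(ids, NULL))
    tgt <- group_labels == target_group
    m[enriched_ids, tgt] <- m[enriched_ids, tgt] * fold
    m
  })
  structure(list(values = vals, groups = group_labels,
                 enriched_ids = enriched_ids), class = "expression_matrix")
}

#' Simulate marker genotypes and affection status on a pedigree
#'
#' Founders draw phased two-locus haplotypes at Hardy-Weinberg / linkage
#' equilibrium; transmissions recombine between the disease and marker locus
#' at `theta_true`; affection status is drawn from the model's penetrance
#' vector given the disease genotype.
#'
#' @param ped A [pedigree()] (affection column may be NA; it is overwritten).
#' @param marker_freqs Marker allele frequencies (sum to 1).
#' @param theta_true Recombination fraction in `[0, 0.5]`.
#' @param model A [disease_model()].
#' @param seed RNG seed.
#' @return The pedigree with `affected` filled in and a `genotypes` matrix
#'   (n x 2 marker alleles) attached as attribute, plus attribute
#'   `disease_genotypes` (copies of disease allele) for ground-truth checks.
#' @export
gen_pedigree_genotypes <- function(ped, marker_freqs = c(0.5, 0.5),
                                   theta_true = 0, model = disease_model(),
                                   seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  check_number(theta_true, "theta_true", lower = 0, upper = 0.5)
  q <- marker_freqs / sum(marker_freqs)
  p_d <- model$disease_freq
  n <- nrow(ped)
  with_seed(seed, {
    # phased haplotypes: column 1 paternal, 2 maternal; each entry a pair
    hap_d <- matrix(NA_integer_, n, 2)  # 1 = disease allele, 0 = normal
    hap_m <- matrix(NA_integer_, n, 2)  # marker allele index
    ord <- pedigree_order(ped)
    for (i in ord) {
      if (is.na(ped$father[i])) {  # founder
        hap_d[i, ] <- stats::rbinom(2, 1, p_d)
        hap_m[i, ] <- sample.int(length(q), 2, replace = TRUE, prob = q)
      } else {
        fa <- match(ped$father[i], ped$id)
        mo <- match(ped$mother[i], ped$id)
        for (side in 1:2) {
          par <- if (side == 1) fa else mo
          grand <- sample(1:2, 1)           # which parental haplotype at the
          other <- 3 - grand                # disease locus
          recomb <- stats::runif(1) < theta_true
          hap_d[i, side] <- hap_d[par, grand]
          hap_m[i, side] <- hap_m[par, if (recomb) other else grand]
        }
      }
    }
    d_copies <- rowSums(hap_d)
    pen <- model$penetrance[d_copies + 1]
    ped$affected <- as.integer(stats::runif(n) < pen)
    geno <- cbind(hap_m[, 1], hap_m[, 2])
    attr(ped, "genotypes") <- geno
    attr(ped, "disease_genotypes") <- d_copies
    ped
  })
}
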