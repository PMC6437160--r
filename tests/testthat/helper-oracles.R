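# Independent oracles used across the suite. These deliberately do NOT call
# the package's internal code paths they are checking.

# Closed-form weighted least squares for y = a + b*x with weights w.
wls_oracle <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  b <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  a <- (sy - b * sx) / sw
  c(intercept = a, slope = b)
}

# Exact accessible area of sphere 1 (radius R1) partially buried by sphere 2
# (radius R2) at center distance d: spherical-cap formula.
two_sphere_area_oracle <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# Brute-force pedigree likelihood: exhaustive sum over joint phased
# two-locus genotypes. State s in 1..S codes (paternal, maternal) haplotype;
# haplotype h in 1..H=2k codes disease allele (h-1)%/%k and marker allele
# (h-1)%%k+1. Enumerates with array outer products; independent of the
# package's peeling implementation.
brute_loglik <- function(ped, genotypes, model, marker_freqs, theta) {
  k <- length(marker_freqs)
  q <- marker_freqs / sum(marker_freqs)
  H <- 2L * k
  S <- H * H
  n <- nrow(ped)
  hd <- function(h) (h - 1) %/% k
  hm <- function(h) (h - 1) %% k + 1
  hapfreq <- ifelse(hd(1:H) == 1, model$disease_freq,
                    1 - model$disease_freq) * q[hm(1:H)]
  sp <- function(s) (s - 1) %/% H + 1   # paternal haplotype of state
  sm <- function(s) (s - 1) %% H + 1
  # P(transmitted hap | parent state)
  Tm <- matrix(0, H, S)
  for (s in 1:S) {
    a <- sp(s); b <- sm(s)
    for (fr in c(a, b)) {
      oth <- if (fr == a) b else a
      nr <- fr
      rc <- hd(fr) * k + hm(oth)
      Tm[nr, s] <- Tm[nr, s] + (1 - theta) / 2
      Tm[rc, s] <- Tm[rc, s] + theta / 2
    }
  }
  ev <- sapply(seq_len(n), function(i) {
    sapply(1:S, function(s) {
      d <- hd(sp(s)) + hd(sm(s))
      pen <- if (is.na(ped$affected[i])) 1
             else if (ped$affected[i] == 1) model$penetrance[d + 1]
             else 1 - model$penetrance[d + 1]
      g <- genotypes[i, ]
      mk <- if (any(is.na(g))) 1 else
        as.numeric(all(sort(c(hm(sp(s)), hm(sm(s)))) == sort(as.numeric(g))))
      pen * mk
    })
  })
  joint <- array(1, dim = rep(S, n))
  sl <- function(i) slice.index(joint, i)
  for (i in seq_len(n)) {
    vi <- ev[, i][sl(i)]
    if (is.na(ped$father[i])) {
      vi <- vi * (hapfreq[sp(1:S)] * hapfreq[sm(1:S)])[sl(i)]
    } else {
      fa <- match(ped$father[i], ped$id)
      mo <- match(ped$mother[i], ped$id)
      trans_f <- Tm[cbind(as.vector(sp(1:S)[sl(i)]), as.vector(sl(fa)))]
      trans_m <- Tm[cbind(as.vector(sm(1:S)[sl(i)]), as.vector(sl(mo)))]
      vi <- vi * array(trans_f * trans_m, dim = dim(joint))
    }
    joint <- joint * vi
  }
  log(sum(joint))
}

brute_lod <- function(ped, genotypes, model, marker_freqs, theta) {
  (brute_loglik(ped, genotypes, model, marker_freqs, theta) -
     brute_loglik(ped, genotypes, model, marker_freqs, 0.5)) / log(10)
}

# Small pedigree fixtures (all loop-free, <= 6 members)
ped_trio <- function(aff = c(1, 0, 1)) {
  pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
           mother = c(NA, NA, "m"), affected = aff)
}

ped_nuclear <- function(n_kids = 3, aff = NULL) {
  ids <- c("f", "m", paste0("k", seq_len(n_kids)))
  if (is.null(aff)) aff <- c(1, 0, rep(c(1, 0), length.out = n_kids))
  pedigree(id = ids, father = c(NA, NA, rep("f", n_kids)),
           mother = c(NA, NA, rep("m", n_kids)), affected = aff)
}

ped_three_gen <- function() {
  pedigree(id = c("gf", "gm", "p", "s", "c1", "c2"),
           father = c(NA, NA, "gf", NA, "p", "p"),
           mother = c(NA, NA, "gm", NA, "s", "s"),
           affected = c(1, 0, 1, 0, 1, 0))
}

# Phase-known fully informative pedigree with m non-recombinant meioses
# (grandparents fix the phase of the doubly heterozygous parent).
ped_phase_known <- function(m = 10) {
  ids <- c("gf", "gm", "p", "s", paste0("k", seq_len(m)))
  aff <- c(1, 0, 1, 0, rep(c(1, 0), length.out = m))
  ped <- pedigree(ids,
                  father = c(NA, NA, "gf", NA, rep("p", m)),
                  mother = c(NA, NA, "gm", NA, rep("s", m)),
                  affected = aff)
  g <- rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 2))
  for (i in seq_len(m)) {
    g <- rbind(g, if (aff[4 + i] == 1) c(1, 2) else c(2, 2))
  }
  attr(ped, "genotypes") <- g
  ped
}
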