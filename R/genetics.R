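# Tissue-enrichment gene prioritization (promoter-atlas style) and
# candidate selection.

#' Tissue-enrichment score per promoter
#'
#' `score = log10(max expression in any target-tissue sample + 1) -
#'          log10(median expression across the collection + 1)`,
#' in log10 fold units. By default the median runs over ALL samples
#' (including the target group); set `include_target_in_median = FALSE` to
#' exclude it.
#'
#' @param mat An `expression_matrix` (see [gen_expression_matrix()]) or a
#'   non-negative numeric matrix promoters x samples.
#' @param groups Sample group labels (ignored when `mat` carries its own).
#' @param target_group Tissue label whose max is scored.
#' @param include_target_in_median See above.
#' @return data.frame with `promoter`, `score`.
#' @export
enrichment_score <- function(mat, groups = NULL,
                             target_group = "skeletal_muscle",
                             include_target_in_median = TRUE) {
  if (inherits(mat, "expression_matrix")) {
    groups <- mat$groups
    mat <- mat$values
  }
  if (is.null(groups) || length(groups) != ncol(mat)) {
    stop_input("groups must label every sample (column)")
  }
  if (any(mat < 0)) stop_input("expression values must be non-negative")
  tgt <- groups == target_group
  if (!any(tgt)) stop_input("target group '%s' is empty", target_group)
  if (all(tgt)) stop_input("target group must be a proper subset of samples")
  med_cols <- if (include_target_in_median) rep(TRUE, ncol(mat)) else !tgt
  score <- log10(apply(mat[, tgt, drop = FALSE], 1, max) + 1) -
    log10(apply(mat[, med_cols, drop = FALSE], 1, stats::median) + 1)
  data.frame(promoter = rownames(mat), score = score, row.names = NULL)
}

#' Select enriched candidates and partition by known disease genes
#'
#' Enriched = strictly greater than `threshold` (default 3.0 log10 units,
#' i.e. >1000-fold).
#'
#' @param results Output of [enrichment_score()].
#' @param threshold Strict lower bound on the score.
#' @param known_disease_genes Character vector of promoter/gene ids already
#'   linked to disease.
#' @return List with `enriched`, `known`, `novel` (character vectors) and
#'   `counts` (named integer vector).
#' @export
select_candidates <- function(results, threshold = 3.0,
                              known_disease_genes = character()) {
  enriched <- results$promoter[results$score > threshold]
  known <- intersect(enriched, known_disease_genes)
  novel <- setdiff(enriched, known_disease_genes)
  list(enriched = enriched, known = known, novel = novel,
       counts = c(enriched = length(enriched), known = length(known),
                  novel = length(novel)))
}

# ---- pedigrees and parametric linkage ---------------------------------------

#' Pedigree constructor
#'
#' @param id Unique member ids. @param father,mother Parent ids or NA
#'   (founder); either both or neither must be given.
#' @param sex 1 = male, 2 = female (metadata only).
#' @param affected 1 affected, 0 unaffected, NA unknown.
#' @return A `pedigree` data.frame ordered so parents precede children.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = NA,
                     affected = NA) {
  ped <- data.frame(id = as.character(id),
                    father = as.character(father),
                    mother = as.character(mother),
                    sex = sex, affected = affected,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop_input("duplicate member ids")
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) {
    stop_input("member '%s' has exactly one parent recorded",
               ped$id[which(half)[1]])
  }
  miss <- stats::na.omit(setdiff(c(ped$father, ped$mother), c(ped$id, NA)))
  if (length(miss)) stop_input("missing parent record(s): %s",
                               paste(miss, collapse = ", "))
  ord <- pedigree_order(ped)   # errors on cycles; row order is preserved
  attr(ped, "topo_order") <- ord
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological order (parents first); detects ancestry cycles
pedigree_order <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed & (is.na(ped$father) |
      (ped$father %in% ped$id[placed] & ped$mother %in% ped$id[placed]))
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop_input("pedigree contains an ancestry cycle (members: %s)",
               paste(ped$id[!placed], collapse = ", "))
  }
  ord
}

# TRUE when the pedigree has a (marriage/consanguinity) loop: the bipartite
# graph individuals <-> nuclear families must be a forest.
pedigree_has_loop <- function(ped) {
  nf <- !is.na(ped$father)
  fams <- unique(paste(ped$father[nf], ped$mother[nf], sep = "|"))
  if (!length(fams)) return(FALSE)
  nodes <- c(ped$id, paste0("F:", fams))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) {
    ra <- find(match(a, nodes)); rb <- find(match(b, nodes))
    if (ra == rb) return(TRUE)  # cycle
    parent[ra] <<- rb
    FALSE
  }
  for (f in fams) {
    pr <- strsplit(f, "|", fixed = TRUE)[[1]]
    fam <- paste0("F:", f)
    if (unite(pr[1], fam)) return(TRUE)
    if (unite(pr[2], fam)) return(TRUE)
    kids <- ped$id[!is.na(ped$father) &
                   paste(ped$father, ped$mother, sep = "|") == f]
    for (k in kids) if (unite(k, fam)) return(TRUE)
  }
  FALSE
}

#' Autosomal disease model for parametric linkage
#'
#' @param disease_freq Disease allele frequency.
#' @param penetrance Length-3 vector: P(affected) for 0/1/2 copies of the
#'   disease allele. The default (0.001, 0.999, 0.999) is a near-fully
#'   penetrant dominant model with a 0.001 phenocopy rate.
#' @return A `disease_model`.
#' @export
disease_model <- function(disease_freq = 0.001,
                          penetrance = c(0.001, 0.999, 0.999)) {
  check_number(disease_freq, "disease_freq", lower = 0, upper = 1)
  if (length(penetrance) != 3L || any(penetrance < 0 | penetrance > 1)) {
    stop_input("penetrance must be 3 probabilities in [0,1]")
  }
  structure(list(disease_freq = disease_freq, penetrance = penetrance),
            class = "disease_model")
}

# Haplotype/state coding.
# Haplotype h in 1..H with H = 2*k: disease allele d in {0,1} and marker
# allele m in 1..k, h = d*k + m. Person state s in 1..H^2 codes the ordered
# (paternal, maternal) haplotype pair: s = (h_pat - 1)*H + h_mat.
hap_disease <- function(h, k) (h - 1) %/% k
hap_marker <- function(h, k) (h - 1) %% k + 1

# P(transmitted haplotype | parent state), H x H^2 matrix, recombination th.
transmission_matrix <- function(k, theta) {
  H <- 2L * k
  S <- H * H
  Tm <- matrix(0, H, S)
  for (hp in 1:H) for (hm in 1:H) {
    s <- (hp - 1L) * H + hm
    for (from in c(hp, hm)) {
      other <- if (from == hp) hm else hp
      nr <- (hap_disease(from, k)) * k + hap_marker(from, k)   # = from
      rc <- (hap_disease(from, k)) * k + hap_marker(other, k)  # recombinant
      Tm[nr, s] <- Tm[nr, s] + (1 - theta) / 2
      Tm[rc, s] <- Tm[rc, s] + theta / 2
    }
  }
  Tm
}

# Evidence vector over states for one person: penetrance x marker match.
person_evidence <- function(S, H, k, affected, geno, model) {
  ev <- numeric(S)
  for (s in 1:S) {
    hp <- (s - 1L) %/% H + 1L
    hm <- (s - 1L) %% H + 1L
    d <- hap_disease(hp, k) + hap_disease(hm, k)
    pen <- if (is.na(affected)) 1
           else if (affected == 1) model$penetrance[d + 1]
           else 1 - model$penetrance[d + 1]
    gm <- sort(c(hap_marker(hp, k), hap_marker(hm, k)))
    mk <- if (is.null(geno) || any(is.na(geno))) 1
          else as.numeric(all(gm == sort(geno)))
    ev[s] <- pen * mk
  }
  ev
}

# --- tiny factor algebra for variable elimination over person states -------
fct <- function(vars, arr) list(vars = vars, arr = arr)

fct_multiply <- function(f1, f2, S) {
  vars <- union(f1$vars, f2$vars)
  d <- rep(S, length(vars))
  g <- as.matrix(expand.grid(lapply(d, seq_len), KEEP.OUT.ATTRS = FALSE))
  v1 <- f1$arr[g[, match(f1$vars, vars), drop = FALSE]]
  v2 <- f2$arr[g[, match(f2$vars, vars), drop = FALSE]]
  fct(vars, array(v1 * v2, dim = d))
}

fct_sumout <- function(f, var) {
  j <- match(var, f$vars)
  if (length(f$vars) == 1L) return(fct(character(0), sum(f$arr)))
  keep <- setdiff(seq_along(f$vars), j)
  fct(f$vars[keep], apply(f$arr, keep, sum))
}

# log-likelihood of the pedigree data at recombination fraction theta,
# by variable elimination (exact; children eliminated before parents).
pedigree_loglik <- function(ped, genotypes, model, marker_freqs, theta) {
  k <- length(marker_freqs)
  q <- marker_freqs / sum(marker_freqs)
  H <- 2L * k
  S <- H * H
  p_d <- model$disease_freq
  hapfreq <- vapply(1:H, function(h) {
    ifelse(hap_disease(h, k) == 1, p_d, 1 - p_d) * q[hap_marker(h, k)]
  }, numeric(1))
  prior <- as.vector(outer(hapfreq, hapfreq))  # s = (hp-1)*H + hm, hp slow
  # NB outer(a,b)[i,j] = a[i]b[j] -> vector index i + (j-1)*H: j (maternal)
  # varies slowly. Rebuild explicitly to match s coding (paternal slow):
  prior <- vapply(1:S, function(s) {
    hp <- (s - 1L) %/% H + 1L; hm <- (s - 1L) %% H + 1L
    hapfreq[hp] * hapfreq[hm]
  }, numeric(1))
  Tm <- transmission_matrix(k, theta)
  ids <- ped$id
  factors <- list()
  for (i in seq_len(nrow(ped))) {
    ev <- person_evidence(S, H, k, ped$affected[i],
                          if (is.null(genotypes)) NULL else genotypes[i, ],
                          model)
    if (is.na(ped$father[i])) ev <- ev * prior
    factors[[length(factors) + 1L]] <- fct(ids[i], array(ev, S))
    if (!is.na(ped$father[i])) {
      fa <- ped$father[i]; mo <- ped$mother[i]
      # P(child state | father state, mother state)
      arr <- array(0, c(S, S, S))
      for (s in 1:S) {
        hp <- (s - 1L) %/% H + 1L; hm <- (s - 1L) %% H + 1L
        arr[s, , ] <- outer(Tm[hp, ], Tm[hm, ])
      }
      factors[[length(factors) + 1L]] <- fct(c(ids[i], fa, mo), arr)
    }
  }
  # eliminate children before parents (reverse topological order)
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- pedigree_order(ped)
  log_scale <- 0
  for (v in rev(ids[ord])) {
    has <- vapply(factors, function(f) v %in% f$vars, logical(1))
    grp <- factors[has]
    factors <- factors[!has]
    f <- grp[[1]]
    for (g in grp[-1]) f <- fct_multiply(f, g, S)
    f <- fct_sumout(f, v)
    m <- max(f$arr)
    if (m <= 0) return(-Inf)
    f$arr <- f$arr / m
    log_scale <- log_scale + log(m)
    factors[[length(factors) + 1L]] <- f
  }
  rest <- prod(vapply(factors, function(f) prod(f$arr), numeric(1)))
  log_scale + log(rest)
}

check_mendelian <- function(ped, genotypes) {
  if (is.null(genotypes)) return(invisible(TRUE))
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i]) || any(is.na(genotypes[i, ]))) next
    fa <- match(ped$father[i], ped$id); mo <- match(ped$mother[i], ped$id)
    gf <- genotypes[fa, ]; gm <- genotypes[mo, ]
    if (any(is.na(gf)) || any(is.na(gm))) next
    gc <- genotypes[i, ]
    ok <- (gc[1] %in% gf && gc[2] %in% gm) || (gc[2] %in% gf && gc[1] %in% gm)
    if (!ok) {
      stop_input("Mendelian inconsistency in trio child '%s' (father '%s', mother '%s')",
                 ped$id[i], ped$father[i], ped$mother[i])
    }
  }
  invisible(TRUE)
}

#' Single-marker parametric LOD score
#'
#' `LOD(theta) = log10 L(theta) - log10 L(0.5)`, with the pedigree
#' likelihood computed exactly by peeling (variable elimination) over phased
#' two-locus (disease x marker) genotypes: founders at Hardy-Weinberg and
#' linkage equilibrium, transmissions recombining at `theta`, affection via
#' the model's penetrance vector. Loop-free pedigrees only.
#'
#' @param ped A [pedigree()] (possibly from [gen_pedigree_genotypes()]).
#' @param genotypes n x 2 matrix of marker allele indices (NA = missing);
#'   defaults to the `genotypes` attribute of `ped`.
#' @param model A [disease_model()].
#' @param marker_freqs Marker allele frequencies.
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @return LOD score (a number; 0 exactly at theta = 0.5).
#' @export
lod_single_marker <- function(ped, genotypes = attr(ped, "genotypes"),
                              model = disease_model(),
                              marker_freqs = c(0.5, 0.5), theta) {
  stopifnot(inherits(ped, "pedigree"))
  check_number(theta, "theta", lower = 0, upper = 0.5)
  if (pedigree_has_loop(ped)) {
    stop_input("looped pedigrees are not supported")
  }
  check_mendelian(ped, genotypes)
  if (theta == 0.5) return(0)
  ll <- pedigree_loglik(ped, genotypes, model, marker_freqs, theta)
  ll_null <- pedigree_loglik(ped, genotypes, model, marker_freqs, 0.5)
  (ll - ll_null) / log(10)
}

#' Maximum LOD over a recombination-fraction grid
#'
#' @inheritParams lod_single_marker
#' @param theta_grid Grid of theta values (default 0 to 0.5 by 0.01); ties
#'   break toward the smaller theta.
#' @return List with `theta_hat`, `lod_max`, and the full `lod` vector.
#' @export
max_lod <- function(ped, genotypes = attr(ped, "genotypes"),
                    model = disease_model(), marker_freqs = c(0.5, 0.5),
                    theta_grid = seq(0, 0.5, by = 0.01)) {
  lods <- vapply(theta_grid, function(th) {
    lod_single_marker(ped, genotypes, model, marker_freqs, th)
  }, numeric(1))
  j <- which.max(lods)  # which.max returns the first (smallest theta) tie
  list(theta_hat = theta_grid[j], lod_max = lods[j], theta = theta_grid,
       lod = lods)
}
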