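# CSV/TSV/PED I/O for the pipeline's data artifacts. Dialects:
#   traces:   time_s (or time_min/time_h), absorbance
#   spectra:  wavelength_nm | wavenumber_cm1, one column per condition
#   titration: wavelength_nm, E_<potential>V columns; reference in a comment
#   voltammogram: potential_V, current
#   expression: TSV, first header row group labels
#   pedigree: 6-column PED-like + 2 genotype columns

#' Write / read a kinetic trace CSV
#'
#' @param trace A [kinetic_trace()]. @param path File path.
#' @return `read_trace` returns a [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  df <- data.frame(time = trace$time, absorbance = trace$signal)
  names(df)[1] <- paste0("time_", trace$unit)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength_nm=%s temperature_C=%s ligand_conc_M=%s",
                     trace$wavelength_nm, trace$temperature_C,
                     trace$ligand_conc), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  unit <- sub("^time_", "", names(df)[1])
  gv <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    if (!length(m)) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*=", "", m)))
  }
  kinetic_trace(df[[1]], df[[2]], unit = unit,
                wavelength_nm = gv("wavelength_nm"),
                temperature_C = gv("temperature_C"),
                ligand_conc = gv("ligand_conc_M"))
}

#' Write / read a redox titration CSV
#'
#' Wavelength rows x potential columns; the header row names the potentials
#' and a leading comment line records the reference electrode.
#'
#' @param titration A [redox_titration()]. @param path File path.
#' @export
write_titration <- function(titration, path) {
  df <- data.frame(wavelength_nm = titration$wavelengths,
                   titration$absorbance)
  names(df)[-1] <- sprintf("E_%gV", titration$potentials)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_C=%g reference=%s",
                     titration$temperature_C, titration$reference), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  meta <- readLines(path, n = 1)
  ref <- sub(".*reference=(.*)$", "\\1", meta)  # reference may contain spaces
  temp <- as.numeric(sub(".*temperature_C=([-0-9.]+).*", "\\1", meta))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  pots <- as.numeric(sub("^E_(.*)V$", "\\1", names(df)[-1]))
  redox_titration(pots, df[[1]], as.matrix(df[, -1]), reference = ref,
                  temperature_C = temp)
}

#' Write / read a voltammogram CSV (potential_V, current)
#' @param vg A voltammogram. @param path File path.
#' @export
write_voltammogram <- function(vg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference=%s", vg$reference), con)
  utils::write.csv(data.frame(potential_V = vg$potential,
                              current = vg$net_current),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltammogram
#' @export
read_voltammogram <- function(path) {
  meta <- readLines(path, n = 1)
  ref <- sub(".*reference=([^ ]+).*", "\\1", meta)
  df <- utils::read.csv(path, comment.char = "#")
  out <- list(potential = df$potential_V, net_current = df$current,
              reference = ref)
  class(out) <- "voltammogram"
  out
}

#' Write / read an FTIR map as long-format CSV
#'
#' Columns: x_um, y_um, region, wavenumber_cm1, absorbance.
#' @param map An `ftir_map`. @param path File path.
#' @export
write_ftir_map <- function(map, path) {
  n_wn <- length(map$wavenumber)
  n_px <- nrow(map$spectra)
  df <- data.frame(
    x_um = rep(map$x_um, each = n_wn),
    y_um = rep(map$y_um, each = n_wn),
    region = rep(as.character(map$region), each = n_wn),
    wavenumber_cm1 = rep(map$wavenumber, times = n_px),
    absorbance = as.vector(t(map$spectra))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ftir_map
#' @export
read_ftir_map <- function(path) {
  df <- utils::read.csv(path)
  key <- paste(df$x_um, df$y_um, sep = "_")
  px <- unique(key)
  wn <- sort(unique(df$wavenumber_cm1))
  spectra <- t(vapply(px, function(p) {
    sub <- df[key == p, ]
    sub$absorbance[order(sub$wavenumber_cm1)]
  }, numeric(length(wn))))
  first <- match(px, key)
  out <- list(wavenumber = wn, spectra = spectra,
              region = factor(df$region[first],
                              levels = c("inclusion", "surround", "background")),
              x_um = df$x_um[first], y_um = df$y_um[first],
              composition = NULL)
  class(out) <- "ftir_map"
  out
}

#' Write / read an expression matrix TSV (first header row = group labels)
#' @param mat An `expression_matrix`. @param path File path.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("promoter", mat$groups), collapse = "\t"), con)
  utils::write.table(data.frame(promoter = rownames(mat$values), mat$values),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  df <- utils::read.delim(path, header = FALSE, skip = 1)
  vals <- as.matrix(df[, -1])
  rownames(vals) <- df[[1]]
  colnames(vals) <- NULL
  out <- list(values = vals, groups = hdr[-1], enriched_ids = character())
  class(out) <- "expression_matrix"
  out
}

#' Write / read a pedigree with genotypes (PED-like text)
#'
#' Whitespace-separated columns: family, id, father, mother, sex, affected
#' (+1 offset PED convention: 1 unaffected, 2 affected, 0 unknown), allele1,
#' allele2 (0 = missing).
#' @param ped A [pedigree()] (genotypes from its attribute).
#' @param path File path. @param family Family label.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  g <- attr(ped, "genotypes")
  if (is.null(g)) g <- matrix(0L, nrow(ped), 2)
  g[is.na(g)] <- 0L
  aff <- ifelse(is.na(ped$affected), 0L, ped$affected + 1L)
  df <- data.frame(family, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   ifelse(is.na(ped$sex), 0L, ped$sex), aff, g[, 1], g[, 2])
  utils::write.table(df, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          colClasses = c(rep("character", 4),
                                         rep("integer", 4)))
  ped <- pedigree(id = df[[2]],
                  father = ifelse(df[[3]] == "0", NA, df[[3]]),
                  mother = ifelse(df[[4]] == "0", NA, df[[4]]),
                  sex = df[[5]],
                  affected = ifelse(df[[6]] == 0L, NA_integer_, df[[6]] - 1L))
  g <- as.matrix(df[, 7:8])
  g[g == 0L] <- NA_integer_
  # reorder genotypes to the (possibly resorted) pedigree rows
  attr(ped, "genotypes") <- g[match(ped$id, df[[2]]), , drop = FALSE]
  ped
}

#' Write / read a spectral basis as CSV (one column per state)
#' @param basis An [mb_basis()]. @param path File path.
#' @export
write_basis <- function(basis, path) {
  df <- data.frame(wavelength_nm = basis$wavelengths, basis$epsilon)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  df <- utils::read.csv(path)
  eps <- as.matrix(df[, -1])
  out <- list(wavelengths = df[[1]], epsilon = eps)
  class(out) <- "mb_basis"
  out
}
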