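#' Read an externally computed per-read-species property table
#'
#' Folding or binding energies of read species are computed outside the
#' package (e.g. minimum free folding energies from RNAfold with DNA
#' parameters at the library annealing temperature) and consumed here as
#' a lookup table keyed by the exact read sequence ("species").
#'
#' @param path TSV with three columns: species sequence, property name,
#'   numeric value. A header line is optional.
#' @return Long tibble `species`, `property`, `value`.
#' @export
read_property_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  offset <- 0L
  if (length(lines) && grepl("^species\t", lines[1])) {
    lines <- lines[-1]
    offset <- 1L
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  bad_shape <- lengths(parts) < 3L
  if (any(bad_shape)) {
    abort(sprintf("malformed property row at line %d",
                  which(bad_shape)[1] + offset))
  }
  value_chr <- vapply(parts, `[[`, character(1), 3L)
  value <- suppressWarnings(as.numeric(value_chr))
  if (anyNA(value)) {
    abort(sprintf("non-numeric property value at line %d: '%s'",
                  which(is.na(value))[1] + offset,
                  value_chr[which(is.na(value))[1]]))
  }
  tibble(
    species = vapply(parts, `[[`, character(1), 1L),
    property = vapply(parts, `[[`, character(1), 2L),
    value = value
  )
}

#' Look up one property for a vector of read species
#'
#' Absent species yield `NA` (an explicit missing marker, never zero).
#'
#' @param properties Tibble from [read_property_table()].
#' @param species Character vector of read sequences.
#' @param property Property name to extract.
#' @return Numeric vector aligned with `species`, `NA` where missing.
#' @export
property_lookup <- function(properties, species, property) {
  sub <- properties[properties$property == property, ]
  sub$value[match(species, sub$species)]
}

#' Fraction of queried species present in a property table
#'
#' @inheritParams property_lookup
#' @return Matched species / total distinct queried species.
#' @export
property_coverage <- function(properties, species, property) {
  species <- unique(species)
  if (!length(species)) return(NA_real_)
  mean(!is.na(property_lookup(properties, species, property)))
}
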