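#' Parse an AAindex-format matrix record into a contact potential
#'
#' Reads one AAindex matrix entry (header lines `H`/`D`/..., an
#' `M rows = ..., cols = ...` line, a triangular or square numeric body and a
#' `//` terminator) and returns the fully symmetrized 20x20 residue-pair
#' contact-energy table.
#'
#' @param text The record as a single string, a character vector of lines, or
#'   a path to a file containing the record.
#' @return An object of class `contact_potential`: a list with elements
#'   `source_id` (the `H` identifier), `energies` (symmetric 20x20 numeric
#'   matrix with one-letter row/column names, RT units) and `min_energy`
#'   (minimum over all 210 unordered pairs).
#' @examples
#' pot <- mj_potential()
#' pot$min_energy
#' pot$energies["C", "C"]
#' @seealso [mj_potential()], [spring_constant()], [write_aaindex()]
#' @export
parse_aaindex_matrix <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)

  h <- grep("^H ", lines, value = TRUE)
  source_id <- if (length(h)) trimws(sub("^H ", "", h[1])) else NA_character_

  m_idx <- grep("^M ", lines)
  if (length(m_idx) != 1)
    stop("malformed AAindex record: expected exactly one 'M rows = ..., cols = ...' line")
  m <- regmatches(lines[m_idx],
                  regexec("rows\\s*=\\s*([A-Z]+)\\s*,\\s*cols\\s*=\\s*([A-Z]+)", lines[m_idx]))[[1]]
  if (length(m) != 3)
    stop("malformed 'M' header line: ", lines[m_idx])
  rows_aa <- strsplit(m[2], "")[[1]]
  cols_aa <- strsplit(m[3], "")[[1]]
  if (length(rows_aa) != 20 || length(cols_aa) != 20 ||
      !setequal(rows_aa, .STD_AA) || !setequal(cols_aa, .STD_AA))
    stop("AAindex alphabet must be the 20 standard amino acids; got rows = ",
         m[2], ", cols = ", m[3])

  end <- grep("^//", lines)
  end <- if (length(end)) min(end[end > m_idx]) else length(lines) + 1
  body <- lines[seq(m_idx + 1, end - 1)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 20)
    stop("expected 20 matrix body rows, found ", length(body))

  E <- matrix(NA_real_, 20, 20, dimnames = list(rows_aa, cols_aa))
  for (i in seq_len(20)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (anyNA(vals))
      stop("non-numeric cell in matrix body line ", i, ": '", body[i], "'")
    if (length(vals) == i) {            # lower triangle (AAindex convention)
      E[i, seq_len(i)] <- vals
    } else if (length(vals) == 20) {    # full square row
      E[i, ] <- vals
    } else {
      stop("matrix body line ", i, " has ", length(vals),
           " values; expected ", i, " (triangular) or 20 (square)")
    }
  }
  # symmetrize from whichever triangle was populated
  for (i in seq_len(20)) for (j in seq_len(20)) {
    if (is.na(E[i, j])) E[i, j] <- E[j, i]
    if (is.na(E[i, j])) stop("cell (", rows_aa[i], ",", cols_aa[j], ") missing")
  }
  if (max(abs(E - t(E))) > 0)
    stop("matrix body is not symmetric after reflection")

  ord <- order(match(rows_aa, .STD_AA))
  E <- E[ord, ord]
  structure(list(source_id = source_id, energies = E, min_energy = min(E)),
            class = "contact_potential")
}

#' The packaged Miyazawa-Jernigan contact potential (AAindex MIYS960101)
#'
#' Loads the residue-residue contact-energy table of Miyazawa & Jernigan
#' (1996), J. Mol. Biol. 256:623-644 (upper half of their Table 3; AAindex
#' identifier MIYS960101), shipped with the package. Energies are in RT units
#' and all 210 unordered pairs are negative (attractive), with the strongest
#' contact between two leucines.
#'
#' @return A `contact_potential` object.
#' @export
mj_potential <- function() {
  parse_aaindex_matrix(system.file("extdata", "MIYS960101.txt",
                                   package = "pspgnm", mustWork = TRUE))
}

#' Spring constant for a residue pair
#'
#' Converts contact energies into Hookean spring stiffnesses. Covalently
#' bonded neighbours (|i-j| = 1 along the chain) always get the stiffest
#' spring, `exp(-(min_energy - 1))`, regardless of residue identity. For
#' non-bonded contacts the default `boltzmann_negated` convention returns
#' `exp(-MJ_ij)`, so that more favourable (more negative) contact energies
#' give stiffer springs and hence lower distance fluctuations; the
#' `literal_eq2` convention returns `exp(+MJ_ij)` instead (see the methods
#' vignette for why the negated form is the default).
#'
#' @param potential A `contact_potential`.
#' @param aa_i,aa_j One-letter residue codes (vectorized, recycled).
#' @param bonded Logical; covalent backbone neighbours.
#' @param convention `"boltzmann_negated"` (default) or `"literal_eq2"`.
#' @return Strictly positive stiffness value(s), symmetric in `(aa_i, aa_j)`.
#' @export
spring_constant <- function(potential, aa_i, aa_j, bonded = FALSE,
                            convention = c("boltzmann_negated", "literal_eq2")) {
  stopifnot(inherits(potential, "contact_potential"))
  convention <- match.arg(convention)
  bad <- setdiff(unique(c(aa_i, aa_j)), .STD_AA)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  n <- max(length(aa_i), length(aa_j), length(bonded))
  aa_i <- rep_len(aa_i, n); aa_j <- rep_len(aa_j, n); bonded <- rep_len(bonded, n)
  e <- potential$energies[cbind(aa_i, aa_j)]
  k <- if (convention == "boltzmann_negated") exp(-e) else exp(e)
  k[bonded] <- exp(-(potential$min_energy - 1))
  k
}

#' Serialize a contact potential back to AAindex matrix format
#'
#' Writes the lower triangle at full precision so that re-parsing with
#' [parse_aaindex_matrix()] reproduces every entry exactly.
#'
#' @param potential A `contact_potential`.
#' @param file Path to write to, or `NULL` to return the lines invisibly.
#' @return The record lines, invisibly.
#' @export
write_aaindex <- function(potential, file = NULL) {
  stopifnot(inherits(potential, "contact_potential"))
  aa <- rownames(potential$energies)
  alpha <- paste(aa, collapse = "")
  lines <- c(paste("H", potential$source_id),
             sprintf("M rows = %s, cols = %s", alpha, alpha))
  for (i in seq_along(aa))
    lines <- c(lines, paste(format(potential$energies[i, seq_len(i)], digits = 17),
                            collapse = " "))
  lines <- c(lines, "//")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.contact_potential <- function(x, ...) {
  cat("Contact potential", x$source_id, "\n")
  cat("  210 unordered residue pairs; min energy", x$min_energy, "RT\n")
  invisible(x)
}
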