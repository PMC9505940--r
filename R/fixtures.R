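# Deterministic synthetic structures and benchmark tables. Everything here is
# reproducible from (arguments, seed) alone and is labelled synthetic; the
# geometries are idealized C-alpha traces, not physical decoys.

# run code with a private RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic C-alpha chain
#'
#' Geometries: `ideal_helix` (rise 1.5 A, radius 2.3 A, 100 degrees per
#' residue; guarantees |i-j| in 2..5 contacts within 9 A, a connected
#' non-trivial network), `perturbed_helix` (helix plus Gaussian coordinate
#' noise), `extended` (straight line at `spacing` A per residue) and
#' `random_compact` (confined 3.8 A random walk). Synthetic B-factors are an
#' affine transform of the uniform-spring network MSF plus seeded noise, so
#' fluctuation/B-factor agreement has a known positive sign.
#'
#' @param n_residues Chain length (>= 4).
#' @param geometry One of `"ideal_helix"`, `"perturbed_helix"`, `"extended"`,
#'   `"random_compact"`.
#' @param seed Integer seed; fully determines the output.
#' @param sequence Optional explicit residue string (one-letter codes);
#'   random otherwise.
#' @param spacing Inter-residue spacing for `extended` (default 3.8 A).
#' @param perturb_sd Coordinate noise SD for `perturbed_helix` (default 0.3 A).
#' @return A `cg_structure` with chain "A" and synthetic B-factors.
#' @examples
#' helix <- make_toy_chain(25, seed = 1)
#' nrow(enumerate_contacts(helix, rc = 9))
#' @export
make_toy_chain <- function(n_residues = 25,
                           geometry = c("ideal_helix", "perturbed_helix",
                                        "extended", "random_compact"),
                           seed = 1, sequence = NULL, spacing = 3.8,
                           perturb_sd = 0.3) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 4)
  with_seed(seed, {
    resid <- if (!is.null(sequence)) {
      s <- toupper(strsplit(sequence, "")[[1]])
      if (length(s) != n_residues || !all(s %in% .STD_AA))
        stop("sequence must be ", n_residues, " standard one-letter codes")
      s
    } else sample(.STD_AA, n_residues, replace = TRUE)

    i <- seq_len(n_residues) - 1
    xyz <- switch(geometry,
      ideal_helix = ,
      perturbed_helix = {
        theta <- i * 100 * pi / 180
        cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
      },
      extended = cbind(spacing * i, 0 * i, 0 * i),
      random_compact = {
        r_conf <- 3.8 * n_residues^(1 / 3)
        p <- matrix(0, n_residues, 3)
        for (k in 2:n_residues) {
          step <- stats::rnorm(3)
          # bias the walk back toward the origin once outside the confinement
          if (sqrt(sum(p[k - 1, ]^2)) > r_conf) step <- step - 0.8 * p[k - 1, ] / r_conf
          p[k, ] <- p[k - 1, ] + 3.8 * step / sqrt(sum(step^2))
        }
        p
      })
    if (geometry == "perturbed_helix")
      xyz <- xyz + matrix(stats::rnorm(3 * n_residues, sd = perturb_sd),
                          n_residues, 3)

    s <- structure(list(structure_id = sprintf("SYN%04d", seed),
                        chain_id = "A", resno = seq_len(n_residues),
                        insert = rep("", n_residues), resid = resid,
                        xyz = xyz, bfactors = NULL),
                   class = "cg_structure")
    # synthetic B-factors: affine uniform-spring MSF + seeded noise
    k <- matrix(0, n_residues, n_residues)
    k[abs(row(k) - col(k)) == 1] <- 1
    cc <- enumerate_contacts(s, rc = 9)
    k[cc] <- 1; k[cc[, c(2, 1), drop = FALSE]] <- 1
    modes <- decompose(kirchhoff_from_springs(k))
    msf <- residue_msf(pseudo_inverse(modes, modes$n - modes$zero_mode_count))
    s$bfactors <- round(10 + 30 * msf / max(msf) +
                          stats::rnorm(n_residues, sd = 0.5), 2)
    s
  })
}

#' Write a coarse-grained structure as a PDB file
#'
#' @param structure A `cg_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "cg_structure"))
  n <- length(structure$resid)
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.vector(t(structure$xyz)),
                   resno = structure$resno,
                   resid = bio3d::aa123(structure$resid),
                   insert = ifelse(structure$insert == "", "", structure$insert),
                   chain = rep(structure$chain_id, n),
                   elety = rep("CA", n),
                   o = rep(1, n),
                   b = structure$bfactors %||% rep(0, n))
  invisible(file)
}

#' PDB text of a coarse-grained structure
#'
#' @param structure A `cg_structure`.
#' @return Character vector of PDB lines.
#' @export
pdb_text <- function(structure) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  write_pdb(structure, tf)
  readLines(tf)
}

#' Generate a wildtype/mutant fixture pair
#'
#' The mutant shares every coordinate with the wildtype and differs only in
#' the residue type at the mutation position. Optionally also emits an
#' "independent reverse structure": the mutant with Gaussian coordinate noise
#' of SD `reverse_sd`, emulating a separately solved mutant crystal.
#'
#' @param n_residues,geometry,seed,sequence Passed to [make_toy_chain()].
#' @param position Author position to mutate; default: an interior position
#'   drawn from the seed (never within 3 residues of either terminus).
#' @param mut_res Mutant residue; default: drawn from the seed, different
#'   from the wildtype residue.
#' @param reverse_sd If > 0, include a coordinate-perturbed mutant (`reverse`).
#' @return List with `wt`, `mut`, `spec` and (optionally) `reverse`.
#' @export
make_mutant_pair <- function(n_residues = 25, seed = 1,
                             geometry = "ideal_helix", sequence = NULL,
                             position = NULL, mut_res = NULL, reverse_sd = 0) {
  wt <- make_toy_chain(n_residues = n_residues, geometry = geometry,
                       seed = seed, sequence = sequence)
  with_seed(seed + 10000L, {
    if (is.null(position))
      position <- sample(seq(4, n_residues - 3), 1)
    idx <- position_index(wt, position)
    if (idx == 0L) stop("position ", position, " not in fixture chain")
    wt_res <- wt$resid[idx]
    if (is.null(mut_res))
      mut_res <- sample(setdiff(.STD_AA, wt_res), 1)
    spec <- mutation_spec("A", wt_res, position, mut_res)
    mut <- apply_mutation(wt, spec)
    out <- list(wt = wt, mut = mut, spec = spec)
    if (reverse_sd > 0) {
      rev_st <- mut
      rev_st$xyz <- mut$xyz + matrix(stats::rnorm(3 * n_residues, sd = reverse_sd),
                                     n_residues, 3)
      rev_st$structure_id <- paste0(mut$structure_id, "_rev")
      out$reverse <- rev_st
    }
    out
  })
}

#' Generate a synthetic benchmark mutation table
#'
#' Temperatures cluster around 25 degrees C and pH around 7 (the conditions
#' under which most stability measurements are made), with deliberate
#' out-of-range and missing-value rows for filter tests. The generator's own
#' bookkeeping of which rows fall inside the default 24-26 C x 6.8-7.2 pH
#' window is attached as `attr(x, "in_range")`.
#'
#' @param n_records Number of rows (>= 1).
#' @param seed Integer seed.
#' @param file Optional path to also write the CSV.
#' @return data.frame with columns `pdb_id`, `chain`, `mutation`,
#'   `temperature`, `ph`, `exp_ddg`; attributes `in_range` (logical vector)
#'   and `csv` (the text lines).
#' @export
make_benchmark_table <- function(n_records = 50, seed = 1, file = NULL) {
  stopifnot(n_records >= 1)
  with_seed(seed, {
    wt <- sample(.STD_AA, n_records, replace = TRUE)
    mut <- vapply(wt, function(a) sample(setdiff(.STD_AA, a), 1), "")
    pos <- sample(5:95, n_records, replace = TRUE)
    grp <- sample(c("in", "out", "missing"), n_records, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    temperature <- round(ifelse(grp == "out",
                                stats::rnorm(n_records, 37, 6),
                                stats::rnorm(n_records, 25, 0.6)), 1)
    ph <- round(ifelse(grp == "out",
                       stats::rnorm(n_records, 5.5, 1.2),
                       stats::rnorm(n_records, 7, 0.1)), 2)
    temperature[grp == "missing"] <- NA
    ph[grp == "missing" & stats::runif(n_records) < 0.5] <- NA
    df <- data.frame(pdb_id = sprintf("SYN%04d", sample(1:40, n_records, TRUE)),
                     chain = "A",
                     mutation = paste0(wt, pos, mut),
                     temperature = temperature, ph = ph,
                     exp_ddg = round(stats::rnorm(n_records, -1, 1.5), 2),
                     stringsAsFactors = FALSE)
    in_range <- !is.na(df$temperature) & !is.na(df$ph) &
      df$temperature >= 24 & df$temperature <= 26 &
      df$ph >= 6.8 & df$ph <= 7.2
    csv <- c(paste(names(df), collapse = ","),
             apply(df, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)),
                                            collapse = ",")))
    if (!is.null(file)) writeLines(csv, file)
    attr(df, "in_range") <- in_range
    attr(df, "csv") <- csv
    df
  })
}
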