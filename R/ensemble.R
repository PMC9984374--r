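#' Conformer ensemble container
#'
#' Holds a trajectory of conformers of one molecule: per-frame Cartesian
#' coordinates (Angstrom), the shared species vector, per-frame potential
#' energies (kcal/mol) and the sampling temperature (K).
#'
#' @param coords list of n_atoms x 3 numeric matrices, one per frame.
#' @param species character vector of element symbols, one per atom.
#' @param energy numeric vector of per-frame energies, same length as `coords`.
#' @param temperature sampling temperature in Kelvin.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, species, energy, temperature = 300) {
  if (length(coords) == 0) abort("ensemble must contain at least one frame")
  if (length(energy) != length(coords)) {
    abort("`energy` must have one value per frame")
  }
  n_at <- vapply(coords, nrow, integer(1))
  if (any(n_at != length(species))) {
    bad <- which(n_at != length(species))[1]
    abort(sprintf("frame %d has %d atoms but species vector has %d",
                  bad, n_at[bad], length(species)))
  }
  structure(
    list(coords = coords, species = as.character(species),
         energy = as.numeric(energy), temperature = temperature),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames, %d atoms (%s), T = %g K\n",
              length(x$coords), length(x$species),
              paste(sort(unique(x$species)), collapse = ","), x$temperature))
  cat(sprintf("  energy range [%.4f, %.4f] kcal/mol\n",
              min(x$energy), max(x$energy)))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$coords)

#' Write an ensemble to an extended-XYZ trajectory file
#'
#' One block per frame: atom count, a comment line carrying
#' `Properties=species:S:1:pos:R:3 energy=<float>`, then one
#' `species x y z` line per atom. Coordinates are printed with 8 decimals.
#'
#' @param ensemble a [conformer_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(ensemble$species)
  for (i in seq_along(ensemble$coords)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("Properties=species:S:1:pos:R:3 energy=%.10g Temperature=%g",
                       ensemble$energy[i], ensemble$temperature), con)
    xyz <- ensemble$coords[[i]]
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f",
                       ensemble$species, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory into a conformer ensemble
#'
#' Requires a per-frame `energy=<float>` key on each comment line and a
#' consistent atom count across frames.
#'
#' @param path file path of an extended-XYZ trajectory.
#' @return a [conformer_ensemble].
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    abort(sprintf("'%s' is empty: refusing to build an empty ensemble", path))
  }
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
  coords <- list(); energies <- numeric(0); species <- NULL; temperature <- 300
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("frame %d: expected an atom count, got '%s'", frame, lines[i]))
    }
    if (i + 1L + n > length(lines)) {
      abort(sprintf("frame %d: truncated block (%d atom lines expected)", frame, n))
    }
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("(?i)\\benergy=([-+0-9.eE]+)", comment, perl = TRUE))[[1]]
    if (length(m) < 2) {
      abort(sprintf("frame %d: comment line lacks required key 'energy='", frame))
    }
    energies <- c(energies, as.numeric(m[2]))
    mt <- regmatches(comment, regexec("(?i)\\btemperature=([-+0-9.eE]+)", comment, perl = TRUE))[[1]]
    if (length(mt) >= 2) temperature <- as.numeric(mt[2])
    at <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    sp <- vapply(at, `[`, character(1), 1)
    xyz <- matrix(as.numeric(unlist(lapply(at, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) abort(sprintf("frame %d: malformed coordinate line", frame))
    if (is.null(species)) {
      species <- sp
    } else if (length(sp) != length(species)) {
      abort(sprintf("frame %d: atom count %d differs from first frame (%d)",
                    frame, length(sp), length(species)))
    }
    coords[[frame]] <- xyz
    i <- i + 2L + n
  }
  conformer_ensemble(coords, species, energies, temperature)
}

#' Tabulate an ensemble as a tidy tibble
#'
#' @param x a [conformer_ensemble].
#' @param ... unused.
#' @return a tibble with columns frame, atom, species, x, y, z, energy.
#' @export
tidy.conformer_ensemble <- function(x, ...) {
  ens <- x
  n <- length(ens$species)
  purrr::map_dfr(seq_along(ens$coords), function(i) {
    tibble::tibble(frame = i, atom = seq_len(n), species = ens$species,
                   x = ens$coords[[i]][, 1], y = ens$coords[[i]][, 2],
                   z = ens$coords[[i]][, 3], energy = ens$energy[i])
  })
}
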