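# Coordinate and results I/O. XYZ carries the box on the comment line
# ("box a b c"); PDB carries it in a CRYST1 record. Coordinates are written
# in Angstrom at the format's native precision (PDB: 3 decimals).

#' Write a system (or trajectory) as XYZ
#'
#' The comment line encodes the box as `box a b c`. An `md_trajectory`
#' writes one XYZ block per frame.
#'
#' @param x a [particle_system()] or `md_trajectory`.
#' @param path output file.
#' @param system for a trajectory: the template system supplying species
#'   and box.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, system = NULL) {
  if (inherits(x, "md_trajectory")) {
    if (is.null(system)) stop("writing a trajectory requires the template system")
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(dim(x$frames)[1])) {
      writeLines(xyz_block(x$frames[f, , ], system$species, system$box,
                           sprintf("box %.8g %.8g %.8g frame %d lambda %g",
                                   system$box[1], system$box[2],
                                   system$box[3], f, x$lambda)), con)
    }
    return(invisible(path))
  }
  stopifnot(inherits(x, "particle_system"))
  writeLines(xyz_block(x$positions, x$species, x$box,
                       sprintf("box %.8g %.8g %.8g", x$box[1], x$box[2],
                               x$box[3])), path)
  invisible(path)
}

xyz_block <- function(pos, species, box, comment) {
  c(as.character(nrow(pos)), comment,
    sprintf("%-3s %14.8f %14.8f %14.8f", species, pos[, 1], pos[, 2],
            pos[, 3]))
}

#' Read an XYZ file
#'
#' Box lengths are taken from a `box a b c` specification on the comment
#' line, or from the `box` argument.
#'
#' @param path input file (first frame of a multi-frame file).
#' @param box optional box lengths overriding the comment line.
#' @param solute optional solute index set to attach.
#' @return A [particle_system()].
#' @export
read_xyz <- function(path, box = NULL, solute = integer(0)) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ at line 1: atom count expected")
  if (length(lines) < 2 + n) {
    stop(sprintf("malformed XYZ: %d atoms declared, file has %d atom lines",
                 n, length(lines) - 2))
  }
  m <- regmatches(lines[2],
                  regexec("box\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                          lines[2]))[[1]]
  if (length(m) == 4) {
    file_box <- as.numeric(m[2:4])
    if (is.null(box)) box <- file_box
  }
  if (is.null(box)) {
    stop("no box: XYZ comment line carries no 'box a b c' and none was given")
  }
  species <- character(n)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[2 + i]), "\\s+")[[1]]
    if (length(toks) < 4) {
      stop(sprintf("malformed XYZ at line %d: species x y z expected", 2 + i))
    }
    species[i] <- toks[1]
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("malformed XYZ at line %d: non-numeric coordinate", 2 + i))
    }
    pos[i, ] <- xyz
  }
  particle_system(pos, species, box, solute = solute)
}

#' Write a system as PDB
#'
#' Writes a CRYST1 record for the box and one HETATM record per atom, with
#' the species label in the element columns (77-78). Serials are 1-based.
#'
#' @param system a [particle_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  b <- system$box
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            b[1], b[2], b[3], 90, 90, 90),
    sprintf("HETATM%5d %-4s MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(n_atoms(system)),
            substr(system$species, 1, 4), 1L,
            system$positions[, 1], system$positions[, 2],
            system$positions[, 3],
            substr(system$species, 1, 2)),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM fixed-width records; the element is taken from
#' columns 77-78 with the atom name as fallback. The box comes from the
#' CRYST1 record.
#'
#' @param path input file.
#' @param require_box error if no CRYST1 record is present (default TRUE;
#'   a periodic run cannot proceed without a box).
#' @param solute optional solute index set to attach.
#' @return A [particle_system()] (box NA-filled with
#'   `require_box = FALSE` and no CRYST1; such a system cannot be used
#'   periodically).
#' @export
read_pdb <- function(path, require_box = TRUE, solute = integer(0)) {
  lines <- readLines(path)
  box <- NULL
  cr <- grep("^CRYST1", lines)
  if (length(cr)) {
    box <- suppressWarnings(as.numeric(c(substr(lines[cr[1]], 7, 15),
                                         substr(lines[cr[1]], 16, 24),
                                         substr(lines[cr[1]], 25, 33))))
    if (anyNA(box)) {
      stop(sprintf("malformed CRYST1 record at line %d", cr[1]))
    }
  } else if (require_box) {
    stop("no box: PDB file has no CRYST1 record, which a periodic run requires")
  }
  at <- grep("^(ATOM  |HETATM)", lines)
  if (!length(at)) stop("no ATOM/HETATM records found")
  n <- length(at)
  pos <- matrix(NA_real_, n, 3)
  species <- character(n)
  for (q in seq_len(n)) {
    ln <- lines[at[q]]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop(sprintf("malformed coordinate field at line %d", at[q]))
    }
    pos[q, ] <- xyz
    el <- trimws(substr(ln, 77, 78))
    if (!nzchar(el)) el <- trimws(substr(ln, 13, 16))
    if (!nzchar(el)) {
      stop(sprintf("no element or atom name at line %d", at[q]))
    }
    species[q] <- el
  }
  if (is.null(box)) box <- rep(1e6, 3)   # effectively non-periodic
  particle_system(pos, species, box, solute = solute)
}

#' Write per-window free energy results as CSV
#'
#' One row per (repeat, window) with the window's lambda interval and BAR
#' estimate.
#'
#' @param result a `free_energy_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  K <- length(result$schedule)
  df <- expand.grid(window = seq_len(K - 1),
                    repeat_ = seq_len(result$n_repeats))
  df$lambda_lo <- result$schedule[df$window]
  df$lambda_hi <- result$schedule[df$window + 1]
  df$dg <- result$per_window[cbind(df$repeat_, df$window)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a result or cycle ledger as JSON
#'
#' @param x a `free_energy_result` or `cycle_ledger`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "cycle_ledger")) {
    out <- list(legs = lapply(x$legs, function(l) list(value = l$value,
                                                       sd = l$sd)),
                closure = x$closure, propagated_error = x$propagated_error)
  } else if (inherits(x, "free_energy_result")) {
    out <- list(dg = x$dg, sd = x$sd, per_repeat = x$per_repeat,
                schedule = x$schedule, scheme = x$scheme,
                estimator = x$estimator)
  } else stop("unsupported object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
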