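#' Read and write XYZ files
#'
#' Standard (multi-frame) XYZ: an atom-count line, a comment line, then
#' `element x y z` rows, repeated per frame. Coordinates are written with
#' six decimal places; round-trips preserve them to that precision.
#'
#' @param path file path.
#' @return `read_xyz`: a list of [conformation()]s (one per frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  out <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("malformed atom-count line %d: '%s'", pos, lines[pos]),
           call. = FALSE)
    }
    if (pos + 1L + n > length(lines)) {
      stop("truncated XYZ frame", call. = FALSE)
    }
    rows <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) < 4L)) stop("malformed atom row", call. = FALSE)
    elements <- vapply(parts, `[[`, "", 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!all(is.finite(coords))) stop("non-numeric coordinates",
                                      call. = FALSE)
    out[[length(out) + 1L]] <- conformation(coords, elements = elements)
    pos <- pos + 2L + n
  }
  out
}

#' @rdname read_xyz
#' @param confs a [conformation()] or a list of them.
#' @param comment comment-line text (recycled over frames).
#' @return `write_xyz`: `path`, invisibly.
#' @export
write_xyz <- function(confs, path, comment = "") {
  if (inherits(confs, "conformation")) confs <- list(confs)
  comment <- rep_len(comment, length(confs))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(confs)) {
    cf <- as_conformation(confs[[f]])
    el <- if (is.null(cf$elements)) rep("X", cf$n_atoms) else cf$elements
    writeLines(c(as.character(cf$n_atoms), comment[f]), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", el,
                       cf$coordinates[, 1L], cf$coordinates[, 2L],
                       cf$coordinates[, 3L]), con)
  }
  invisible(path)
}

#' Read and write SDF (V2000 molfile) files
#'
#' Minimal V2000 support: coordinates, element symbols and the bond block.
#' Bonds matter here because covalent bonds convert directly into distance
#' constraints at their current lengths (see [bonds_to_constraints()]).
#' V2000 stores coordinates with four decimal places, the round-trip
#' precision.
#'
#' @param path file path.
#' @return `read_sdf`: list of molecules, each a list with `conformation`
#'   and `bonds` (data frame `i`, `j`, `order`, 1-based).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  # split records on $$$$
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) {
    starts <- 1L
    ends <- length(lines) + 1L
  }
  out <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    if (length(rec) < 4L || !any(nzchar(trimws(rec)))) next
    counts <- rec[4L]
    n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(n_atoms) || is.na(n_bonds)) {
      stop(sprintf("malformed counts line in record %d: '%s'", r, counts),
           call. = FALSE)
    }
    atom_rows <- rec[5:(4L + n_atoms)]
    coords <- t(vapply(atom_rows, function(l) {
      as.numeric(c(substr(l, 1L, 10L), substr(l, 11L, 20L),
                   substr(l, 21L, 30L)))
    }, numeric(3), USE.NAMES = FALSE))
    elements <- trimws(substr(atom_rows, 32L, 34L))
    bonds <- if (n_bonds > 0L) {
      bond_rows <- rec[(5L + n_atoms):(4L + n_atoms + n_bonds)]
      b <- t(vapply(bond_rows, function(l) {
        as.integer(c(substr(l, 1L, 3L), substr(l, 4L, 6L),
                     substr(l, 7L, 9L)))
      }, integer(3), USE.NAMES = FALSE))
      if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n_atoms)) {
        stop("bond references atom index out of range", call. = FALSE)
      }
      data.frame(i = b[, 1L], j = b[, 2L], order = b[, 3L])
    } else data.frame(i = integer(0), j = integer(0), order = integer(0))
    out[[length(out) + 1L]] <-
      list(conformation = conformation(coords, elements = elements),
           bonds = bonds)
  }
  out
}

#' @rdname read_sdf
#' @param conf a [conformation()].
#' @param bonds optional bond data frame (`i`, `j`, `order`).
#' @param title molecule title line.
#' @param append append a record to an existing file.
#' @return `write_sdf`: `path`, invisibly.
#' @export
write_sdf <- function(conf, path, bonds = NULL, title = "molecule",
                      append = FALSE) {
  conf <- as_conformation(conf)
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  el <- if (is.null(conf$elements)) rep("C", conf$n_atoms) else conf$elements
  lines <- c(title, "  shakediff", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     conf$n_atoms, nrow(bonds)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            conf$coordinates[, 1L], conf$coordinates[, 2L],
                            conf$coordinates[, 3L], el))
  if (nrow(bonds) > 0L) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j,
                              if (is.null(bonds$order)) 1L else bonds$order))
  }
  lines <- c(lines, "M  END", "$$$$")
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Covalent bonds as distance constraints
#'
#' Converts a bond list to strict distance constraints whose targets are
#' the current bond lengths in the given conformation -- the standard
#' companion set that keeps bonded geometry intact while an end-to-end or
#' mined constraint acts.
#'
#' @param conf a [conformation()].
#' @param bonds data frame with columns `i`, `j` (1-based).
#' @return a [constraint_set()] with one distance constraint per bond.
#' @export
bonds_to_constraints <- function(conf, bonds) {
  conf <- as_conformation(conf)
  constraint_set(lapply(seq_len(nrow(bonds)), function(b) {
    distance_constraint(bonds$i[b], bonds$j[b],
                        measure_distance(conf, bonds$i[b], bonds$j[b]))
  }))
}

#' Load a constraint configuration file
#'
#' YAML or JSON (by extension). Schema: top-level `constraints`, a list of
#' blocks with `kind` (distance/angle/dihedral), `atoms` (1-based indices),
#' `target`, and optional `lower`, `upper`, `slack_max` (default 0 =
#' strict), `schedule` (name); optional top-level `schedules`, a named map
#' of blocks with `beta`, `t0`, `lower_initial`, `upper_initial`,
#' `lower_final`, `upper_final` (the strings `"-inf"`/`"inf"` mean
#' unbounded; a schedule's final bounds default to the constraint's).
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a [constraint_set()]; schedules referenced by name are attached
#'   to their constraints.
#' @export
load_constraints <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else stop("constraint config must be .yaml/.yml/.json", call. = FALSE)
  if (is.null(cfg$constraints)) {
    stop("config field 'constraints' is missing", call. = FALSE)
  }
  num_or_inf <- function(v, default) {
    if (is.null(v)) return(default)
    if (is.character(v)) {
      v <- tolower(v)
      if (v %in% c("inf", "+inf", "unbounded")) return(Inf)
      if (v == "-inf") return(-Inf)
      stop(sprintf("unparseable bound '%s'", v), call. = FALSE)
    }
    as.numeric(v)
  }
  schedules <- lapply(cfg$schedules, function(s) s)
  make_one <- function(blk, idx) {
    where <- sprintf("constraints[%d]", idx)
    kind <- blk$kind
    if (is.null(kind) || !kind %in% c("distance", "angle", "dihedral")) {
      stop(sprintf("%s.kind: must be distance, angle or dihedral", where),
           call. = FALSE)
    }
    atoms <- as.integer(unlist(blk$atoms))
    need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
    if (length(atoms) != need) {
      stop(sprintf("%s.atoms: %s needs %d atom indices", where, kind, need),
           call. = FALSE)
    }
    if (is.null(blk$target)) {
      stop(sprintf("%s.target: missing", where), call. = FALSE)
    }
    target <- as.numeric(blk$target)
    slack <- if (is.null(blk$slack_max)) 0 else as.numeric(blk$slack_max)
    lower <- num_or_inf(blk$lower, NULL)
    upper <- num_or_inf(blk$upper, NULL)
    if (!is.null(lower) && !is.null(upper) && lower > upper) {
      stop(sprintf("%s: lower > upper", where), call. = FALSE)
    }
    sch <- NULL
    if (!is.null(blk$schedule)) {
      sblk <- schedules[[blk$schedule]]
      if (is.null(sblk)) {
        stop(sprintf("%s.schedule: unknown schedule '%s'", where,
                     blk$schedule), call. = FALSE)
      }
      lf <- num_or_inf(sblk$lower_final,
                       if (!is.null(lower)) lower else target - slack)
      uf <- num_or_inf(sblk$upper_final,
                       if (!is.null(upper)) upper else target + slack)
      sch <- bound_schedule(
        beta = if (is.null(sblk$beta)) 10 else as.numeric(sblk$beta),
        t0 = if (is.null(sblk$t0)) 0.5 else as.numeric(sblk$t0),
        lower_initial = num_or_inf(sblk$lower_initial, -Inf),
        upper_initial = num_or_inf(sblk$upper_initial, Inf),
        lower_final = lf, upper_final = uf)
    }
    args <- list(target = target, slack_max = slack,
                 lower_final = lower, upper_final = upper, schedule = sch)
    fun <- switch(kind, distance = distance_constraint,
                  angle = angle_constraint,
                  dihedral = dihedral_constraint)
    do.call(fun, c(as.list(atoms), args))
  }
  constraint_set(lapply(seq_along(cfg$constraints), function(q)
    make_one(cfg$constraints[[q]], q)))
}

#' Write mined constraints to a YAML config
#'
#' @param set a [constraint_set()] of distance constraints.
#' @param path output `.yaml` path.
#' @param seed optional seed recorded in the header comment for
#'   reproducibility.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(set, path, seed = NULL) {
  blocks <- lapply(unclass(set), function(cst) {
    b <- list(kind = cst$kind, atoms = as.list(cst$atoms),
              target = cst$target)
    if (cst$lower_final != cst$target || cst$upper_final != cst$target) {
      b$lower <- cst$lower_final
      b$upper <- cst$upper_final
    }
    b
  })
  header <- sprintf("# shakediff constraints%s",
                    if (is.null(seed)) "" else sprintf(" (seed %d)", seed))
  txt <- yaml::as.yaml(list(constraints = blocks))
  writeLines(c(header, txt), path)
  invisible(path)
}
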