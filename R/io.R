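# Residue names encode the species; bead names encode the role.
species_resname <- c(PO = "POPX", DL = "DLPX", W = "W")

#' Default bead-name roster map
#'
#' Maps coarse-grained bead names to roles: `NH3`/`NC3`/`PO4` headgroup-layer
#' beads, `GL1`/`GL2` ester beads, `C<k>A`/`C<k>B` (and `D<k>B`) chain beads,
#' `W` water. Used by [read_gro()] and [read_pdb()] to rebuild the roster
#' metadata from plain coordinate files.
#'
#' @return Named list: regular expressions on bead names mapped to roles.
#' @export
default_roster_map <- function() {
  list(
    "^(NH3|NC3|PO4)$" = "headgroup",
    "^GL[12]$" = "ester",
    "^[CD][0-9]+[AB]$" = "chain",
    "^W$" = "water"
  )
}

roster_from_names <- function(bead_names, roster_map) {
  roles <- rep(NA_character_, length(bead_names))
  for (pat in names(roster_map)) {
    roles[is.na(roles) & grepl(pat, bead_names)] <- roster_map[[pat]]
  }
  if (any(is.na(roles))) {
    abort(paste0(
      "roster map does not resolve bead name(s): ",
      toString(unique(bead_names[is.na(roles)]))
    ))
  }
  roles
}

# Derive tail_index / bead_index from bead names (GL1/GL2, C3A -> tail 1
# bead 3, C2B -> tail 2 bead 2).
parse_bead_indices <- function(bead, role) {
  tail_index <- rep(NA_integer_, length(bead))
  bead_index <- rep(NA_integer_, length(bead))
  is_ester <- role == "ester"
  tail_index[is_ester] <- as.integer(sub("^GL", "", bead[is_ester]))
  is_chain <- role == "chain"
  tail_index[is_chain] <- ifelse(grepl("A$", bead[is_chain]), 1L, 2L)
  bead_index[is_chain] <- as.integer(sub("^[CD]([0-9]+)[AB]$", "\\1",
                                         bead[is_chain]))
  list(tail_index = tail_index, bead_index = bead_index)
}

#' Write a bead configuration as GRO
#'
#' One GRO file per frame (`<stem>.gro`, or `<stem>_f<k>.gro` for
#' multi-frame configurations), with coordinates converted from the internal
#' Angstrom to GRO's nm. Generation parameters and the seed can be echoed to
#' a JSON sidecar.
#'
#' @param config A [bead_config()].
#' @param path Output path (`.gro`).
#' @param sidecar Optional named list written as `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_gro <- function(config, path, sidecar = NULL) {
  box <- bead_box(config) * .NM_PER_ANGSTROM
  frames <- sort(unique(config$frame))
  stem <- sub("\\.gro$", "", path)
  paths <- character(0)
  for (f in frames) {
    fr <- config[config$frame == f, ]
    p <- if (length(frames) == 1) paste0(stem, ".gro") else
      sprintf("%s_f%d.gro", stem, f)
    lines <- c(
      sprintf("bead configuration, t= %.3f", fr$time[1]),
      sprintf("%5d", nrow(fr)),
      sprintf(
        "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
        (fr$lipid_id %% 100000L),
        species_resname[fr$species],
        substr(fr$bead, 1, 5),
        seq_len(nrow(fr)) %% 100000L,
        fr$x * .NM_PER_ANGSTROM, fr$y * .NM_PER_ANGSTROM,
        fr$z * .NM_PER_ANGSTROM
      ),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
    )
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, paste0(stem, ".json"))
  }
  invisible(paths)
}

#' Read a GRO file into a bead configuration
#'
#' Converts GRO nm coordinates to the internal Angstrom, resolves bead roles
#' through the roster map, and rebuilds lipid ids from residue numbers.
#' Water is retained. z is re-centered so the ester midplane sits at 0.
#'
#' @param path `.gro` file path.
#' @param roster_map Named list of bead-name regular expressions to roles
#'   (default [default_roster_map()]).
#' @return A single-frame [bead_config()] (leaflets assigned).
#' @export
read_gro <- function(path, roster_map = default_roster_map()) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  atoms <- lines[3:(2 + n)]
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  df <- tibble(
    resid = as.integer(substr(atoms, 1, 5)),
    resname = trimws(substr(atoms, 6, 10)),
    bead = trimws(substr(atoms, 11, 15)),
    x = as.numeric(substr(atoms, 21, 28)) / .NM_PER_ANGSTROM,
    y = as.numeric(substr(atoms, 29, 36)) / .NM_PER_ANGSTROM,
    z = as.numeric(substr(atoms, 37, 44)) / .NM_PER_ANGSTROM
  )
  build_config_from_atoms(df, box / .NM_PER_ANGSTROM, roster_map)
}

build_config_from_atoms <- function(df, box_angstrom, roster_map) {
  species_of <- setNames(names(species_resname), species_resname)
  if (any(!df$resname %in% names(species_of))) {
    abort(paste0("unknown residue name(s): ",
                 toString(setdiff(unique(df$resname), names(species_of)))))
  }
  df$species <- unname(species_of[df$resname])
  df$role <- roster_from_names(df$bead, roster_map)
  idx <- parse_bead_indices(df$bead, df$role)
  df$tail_index <- idx$tail_index
  df$bead_index <- idx$bead_index
  df$lipid_id <- ifelse(df$role == "water", 0L, df$resid)
  # Every lipid must carry its two ester beads.
  esters_per <- df |>
    filter(.data$role != "water") |>
    summarise(n_ester = sum(.data$role == "ester"), .by = "lipid_id")
  bad <- esters_per$lipid_id[esters_per$n_ester != 2]
  if (length(bad)) {
    abort(paste0("lipids missing ester beads: ", toString(head(bad, 10))))
  }
  mid <- mean(df$z[df$role == "ester"])
  out <- df |>
    mutate(
      frame = 1L, time = 0, leaflet = NA_character_,
      z = .data$z - mid
    ) |>
    select("frame", "time", "lipid_id", "species", "bead", "role",
           "tail_index", "bead_index", "leaflet", "x", "y", "z")
  assign_leaflets(bead_config(out, box_angstrom))
}

#' Write a bead configuration as PDB
#'
#' Coordinates stay in Angstrom; the box goes to CRYST1; multi-frame
#' configurations become MODEL/ENDMDL blocks.
#'
#' @inheritParams write_gro
#' @param path Output `.pdb` path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(config, path) {
  box <- bead_box(config)
  frames <- sort(unique(config$frame))
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   box[1], box[2], box[3])
  for (f in frames) {
    fr <- config[config$frame == f, ]
    if (length(frames) > 1) lines <- c(lines, sprintf("MODEL     %4d", f))
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(fr)) %% 100000L,
      substr(fr$bead, 1, 4),
      substr(species_resname[fr$species], 1, 4),
      fr$lipid_id %% 10000L,
      fr$x, fr$y, fr$z
    ))
    if (length(frames) > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a (single-frame) PDB file into a bead configuration
#'
#' @inheritParams read_gro
#' @param path `.pdb` file path.
#' @return A single-frame [bead_config()] (leaflets assigned).
#' @export
read_pdb <- function(path, roster_map = default_roster_map()) {
  lines <- readLines(path)
  cryst <- lines[startsWith(lines, "CRYST1")]
  if (length(cryst) == 0) abort("PDB lacks a CRYST1 record (box unknown)")
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
  atoms <- lines[startsWith(lines, "ATOM")]
  df <- tibble(
    bead = trimws(substr(atoms, 13, 16)),
    resname = trimws(substr(atoms, 18, 21)),
    resid = as.integer(substr(atoms, 23, 27)),
    x = as.numeric(substr(atoms, 31, 38)),
    y = as.numeric(substr(atoms, 39, 46)),
    z = as.numeric(substr(atoms, 47, 54))
  )
  build_config_from_atoms(df, box, roster_map)
}

#' Write a scalar map as CSV plus a JSON header
#'
#' The CSV holds the value matrix (rows = x cells, columns = y cells) with
#' masked cells left empty; the `<path>.json` header records the grid
#' specification, descriptor, units, leaflet scope, frame count and the
#' missing-value convention.
#'
#' @param map A `scalar_map`.
#' @param path Output `.csv` path.
#' @return Invisibly, the two paths.
#' @export
write_map_csv <- function(map, path) {
  m <- map_matrix(map)
  utils::write.table(
    m, path, sep = ",", row.names = FALSE, col.names = FALSE, na = ""
  )
  grid <- attr(map, "grid")
  header <- list(
    descriptor = attr(map, "descriptor"), units = attr(map, "units"),
    leaflet = attr(map, "leaflet"), n_frames = attr(map, "map_frames"),
    grid = grid[c("nx", "ny", "ex", "ey", "Lx", "Ly", "stamp_radius")],
    missing_value = "empty cell (masked / not statistically significant)",
    layout = "rows are x cells, columns are y cells; cell centers at (i-0.5)*ex"
  )
  jpath <- paste0(sub("\\.csv$", "", path), ".json")
  jsonlite::write_json(header, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, jpath))
}

#' Read a photobleaching step-count table
#'
#' Expects the CSV schema `label, pct_dl, chi_subunits_per_lipid, n1, n2,
#' n3plus`; probabilities and the reactive mole fraction `chi_star = chi / 2`
#' are derived.
#'
#' @param path CSV path.
#' @return Tibble with the input columns plus `chi_star`, `p1`, `p2`,
#'   `p3plus`.
#' @export
read_step_counts <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("label", "pct_dl", "chi_subunits_per_lipid", "n1", "n2", "n3plus")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("step-count table missing columns: ", toString(missing)))
  }
  df |>
    mutate(
      total = .data$n1 + .data$n2 + .data$n3plus,
      chi_star = .data$chi_subunits_per_lipid / 2,
      p1 = .data$n1 / .data$total,
      p2 = .data$n2 / .data$total,
      p3plus = .data$n3plus / .data$total
    ) |>
    select(-"total")
}

#' Write a fit object as JSON
#'
#' Serializes the scalar components of a fit (estimates, errors, flags) to
#' JSON; list/data components are dropped.
#'
#' @param fit An `isotherm_fit`, `titration_fit`, `ddg_fit`, `efflux_fit` or
#'   `fdimer_fit`.
#' @param path Output `.json` path.
#' @return Invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  keep <- purrr::keep(unclass(fit), function(x) {
    (is.numeric(x) || is.character(x) || is.logical(x)) && length(x) <= 8
  })
  jsonlite::write_json(c(list(class = class(fit)[1]), keep), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
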