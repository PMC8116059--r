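#' Bead configuration container
#'
#' A bead configuration is a tibble with one row per bead per frame and the
#' simulation box stored as an attribute. Columns: `frame` (integer), `time`
#' (arbitrary units, strictly increasing with frame), `lipid_id` (integer, 0
#' for water), `species` (`"PO"`, `"DL"` or `"W"`), `bead`, `role`
#' (`"headgroup"`, `"ester"`, `"chain"`, `"water"`), `tail_index`,
#' `bead_index`, `leaflet` (`"outer"`, `"inner"` or `NA`), and coordinates
#' `x`, `y`, `z` in Angstrom. The box is a length-3 numeric `c(Lx, Ly, Lz)`;
#' x and y are periodic, z is free.
#'
#' @param beads Tibble of beads with the columns above.
#' @param box Numeric length-3, box edges in Angstrom (all > 0).
#' @return A `bead_config` tibble.
#' @export
bead_config <- function(beads, box) {
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("`box` must be three positive finite edge lengths (Angstrom).")
  }
  required <- c(
    "frame", "time", "lipid_id", "species", "bead", "role",
    "tail_index", "bead_index", "leaflet", "x", "y", "z"
  )
  missing <- setdiff(required, names(beads))
  if (length(missing)) {
    abort(paste0("bead table is missing columns: ", toString(missing)))
  }
  if (any(!is.finite(beads$x) | !is.finite(beads$y) | !is.finite(beads$z))) {
    abort("all bead positions must be finite")
  }
  out <- as_tibble(beads)
  attr(out, "box") <- as.numeric(box)
  class(out) <- c("bead_config", class(tibble()))
  out
}

#' Box dimensions of a bead configuration
#'
#' @param config A `bead_config`.
#' @return Numeric `c(Lx, Ly, Lz)` in Angstrom.
#' @export
bead_box <- function(config) {
  box <- attr(config, "box", exact = TRUE)
  if (is.null(box)) abort("`config` has no box attribute; not a bead_config?")
  box
}

# Re-attach bead_config metadata after dplyr verbs strip it.
restore_config <- function(df, config) {
  bead_config(df, bead_box(config))
}

#' Number of frames in a configuration
#' @param config A `bead_config`.
#' @return Integer frame count.
#' @export
n_frames <- function(config) {
  length(unique(config$frame))
}

# Minimum-image displacement along a periodic axis.
pbc_delta <- function(d, L) {
  d - L * round(d / L)
}

# Wrap coordinates into [0, L).
pbc_wrap <- function(v, L) {
  v - L * floor(v / L)
}

#' @export
print.bead_config <- function(x, ...) {
  box <- bead_box(x)
  cat(sprintf(
    "<bead_config> %d beads, %d frame(s), box %.1f x %.1f x %.1f A\n",
    nrow(x), n_frames(x), box[1], box[2], box[3]
  ))
  NextMethod()
}

# Per-lipid ester midpoints (one row per frame x lipid), excluding water.
ester_midpoints <- function(config) {
  config |>
    filter(.data$role == "ester") |>
    summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      species = .data$species[1], leaflet = .data$leaflet[1],
      .by = c("frame", "lipid_id")
    )
}
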