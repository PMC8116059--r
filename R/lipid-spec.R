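#' Coarse-grained lipid bead rosters
#'
#' Bead templates for the two lipid species handled by the pipeline: the
#' long-chain palmitoyl-oleoyl ("PO", C16:0/18:1-like) and short-chain
#' di-lauryl ("DL", C12:0-like) phospholipids. Each lipid is represented at
#' coarse-grained granularity by one headgroup bead, two ester-linkage beads
#' (GL1, GL2) and two acyl tails of equally spaced chain beads (5 beads per
#' tail for PO, 3 for DL, 3 Angstrom spacing).
#'
#' Template coordinates are expressed in a lipid-local frame: the ester
#' midpoint sits at the origin, the headgroup 3 Angstrom above it along the
#' local axis, and the tails extend downward (toward the bilayer midplane
#' once the lipid is placed). Outer-leaflet lipids use the local frame as-is;
#' inner-leaflet lipids are mirrored in z.
#'
#' @param species `"PO"` or `"DL"`.
#' @return A tibble with one row per bead: `bead` (name), `role`
#'   (`"headgroup"`, `"ester"` or `"chain"`), `tail_index` (1, 2 or `NA`),
#'   `bead_index` (position along the tail), and local coordinates
#'   `lx`, `ly`, `lz` in Angstrom.
#' @examples
#' lipid_spec("DL")
#' @export
lipid_spec <- function(species = c("PO", "DL")) {
  species <- match.arg(species)
  n_chain <- if (species == "PO") 5L else 3L
  spacing <- 3 # Angstrom between consecutive chain beads
  head <- tibble(
    bead = "NH3", role = "headgroup", tail_index = NA_integer_,
    bead_index = NA_integer_, lx = 0, ly = 0, lz = 3
  )
  esters <- tibble(
    bead = c("GL1", "GL2"), role = "ester", tail_index = 1:2,
    bead_index = NA_integer_, lx = c(-1.5, 1.5), ly = 0, lz = 0
  )
  chains <- purrr::map_dfr(1:2, function(tail) {
    tibble(
      bead = sprintf("C%d%s", seq_len(n_chain), c("A", "B")[tail]),
      role = "chain", tail_index = as.integer(tail),
      bead_index = seq_len(n_chain),
      lx = c(-1.5, 1.5)[tail], ly = 0,
      lz = -spacing * seq_len(n_chain)
    )
  })
  dplyr::bind_rows(head, esters, chains)
}

#' Nominal acyl tail length of a lipid species
#'
#' Distance from the ester bead to the last chain bead along the lipid axis,
#' in Angstrom (15 for PO, 9 for DL with the default 3 Angstrom bead spacing).
#'
#' @inheritParams lipid_spec
#' @return Length in Angstrom.
#' @export
nominal_tail_length <- function(species = c("PO", "DL")) {
  species <- match.arg(species)
  tmpl <- lipid_spec(species)
  max(abs(tmpl$lz[tmpl$role == "chain"]))
}
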