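#' Generate a lateral-diffusion pseudo-trajectory
#'
#' Extends a single-frame configuration to `n_frames` frames in which each
#' lipid performs an independent lateral Gaussian random walk (rigid
#' translation of all its beads, periodic wrapping in x and y), preserving
#' the internal roster geometry. Water beads stay in place. An optional
#' region bias makes one species statistically accumulate in a named region:
#' a biased lipid inside the region retries a step that would carry it out
#' with probability `1 - escape_prob`.
#'
#' This is transport plumbing for testing mixing and enrichment statistics,
#' not a physical simulator: there are no energetics and no excluded volume.
#'
#' @param config A single-frame [bead_config()] (for a multi-frame input the
#'   last frame is extended).
#' @param n_frames Total number of output frames (>= 1; the first frame is
#'   the input frame).
#' @param step_sd Standard deviation of the per-frame lateral step, Angstrom
#'   (>= 0).
#' @param region_bias Optional list with elements `region` (function of
#'   `(x, y)` returning logical), `species` (`"PO"` or `"DL"`), and
#'   `escape_prob` (probability that a step leaving the region is accepted,
#'   default 0.05).
#' @param seed Optional integer seed.
#' @return A multi-frame [bead_config()] with strictly increasing times.
#' @export
generate_trajectory <- function(config, n_frames, step_sd,
                                region_bias = NULL, seed = NULL) {
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (step_sd < 0) abort("`step_sd` must be >= 0")
  box <- bead_box(config)
  last_frame <- max(config$frame)
  base <- config[config$frame == last_frame, ]
  base$frame <- 1L
  t0 <- base$time[1]
  if (n_frames == 1) return(restore_config(base, config))

  biased_ids <- integer(0)
  escape_prob <- 0.05
  if (!is.null(region_bias)) {
    stopifnot(is.function(region_bias$region))
    escape_prob <- region_bias$escape_prob %||% 0.05
    biased_ids <- unique(base$lipid_id[
      base$species == (region_bias$species %||% "DL") & base$lipid_id > 0
    ])
  }

  lipid_rows <- base[base$lipid_id > 0, ]
  water_rows <- base[base$lipid_id == 0, ]
  ids <- unique(lipid_rows$lipid_id)
  # Reference lateral position of each lipid = its ester midpoint.
  ref <- lipid_rows |>
    filter(.data$role == "ester") |>
    summarise(cx = mean(.data$x), cy = mean(.data$y), .by = "lipid_id") |>
    arrange(match(.data$lipid_id, ids))
  cx <- ref$cx
  cy <- ref$cy

  with_seed(seed, {
    frames <- vector("list", n_frames)
    frames[[1]] <- base
    for (f in 2:n_frames) {
      if (step_sd > 0) {
        dx <- rnorm(length(ids), 0, step_sd)
        dy <- rnorm(length(ids), 0, step_sd)
        if (length(biased_ids)) {
          b <- ids %in% biased_ids
          inside_now <- region_bias$region(cx[b], cy[b])
          nx <- pbc_wrap(cx[b] + dx[b], box[1])
          ny <- pbc_wrap(cy[b] + dy[b], box[2])
          inside_next <- region_bias$region(nx, ny)
          veto <- inside_now & !inside_next &
            (runif(sum(b)) > escape_prob)
          dx[b][veto] <- 0
          dy[b][veto] <- 0
        }
        cx <- pbc_wrap(cx + dx, box[1])
        cy <- pbc_wrap(cy + dy, box[2])
        shift <- tibble(lipid_id = ids, dx = dx, dy = dy)
        moved <- frames[[f - 1]] |>
          filter(.data$lipid_id > 0) |>
          left_join(shift, by = "lipid_id") |>
          mutate(
            x = pbc_wrap(.data$x + .data$dx, box[1]),
            y = pbc_wrap(.data$y + .data$dy, box[2])
          ) |>
          select(-"dx", -"dy")
      } else {
        moved <- frames[[f - 1]] |> filter(.data$lipid_id > 0)
      }
      frames[[f]] <- bind_rows(moved, water_rows) |>
        mutate(frame = as.integer(f), time = t0 + (f - 1))
    }
    restore_config(bind_rows(frames), config)
  })
}
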