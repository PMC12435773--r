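#' Read and zone a per-cell measurement table
#'
#' CSV contract (header mandatory, comma separated, coordinates in um,
#' 0-based plane indices): `cell_id, focus_x, focus_y, plane, center_x,
#' center_y, radius, n_planes, bud_area, mother_area, condition` and
#' optionally `timepoint`.  Applies the mid-stack and mid-to-late-S bud-size
#' gates, classifies each surviving focus, and tallies per condition /
#' timepoint.
#'
#' @param path CSV path.
#' @param stages Cell-cycle stages kept (default `"midlateS"`).
#' @return List with `cells` (the table plus `stage`, `kept`, `zone`
#'   columns) and `tallies` (a [zone_tally()]).
#' @export
zone_cells_csv <- function(path, stages = "midlateS") {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "focus_x", "focus_y", "plane", "center_x", "center_y",
            "radius", "n_planes", "bud_area", "mother_area", "condition")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cells$stage <- cell_cycle_gate(cells$bud_area, cells$mother_area)
  cells$kept <- cells$stage %in% stages &
    midstack_gate(cells$plane, cells$n_planes)
  cells$zone <- NA_integer_
  for (i in which(cells$kept)) {
    nuc <- nucleus_geometry(c(cells$center_x[i], cells$center_y[i]),
                            cells$radius[i], cells$plane[i], cells$n_planes[i])
    z <- tryCatch(classify_zone(c(cells$focus_x[i], cells$focus_y[i]), nuc),
                  error = function(e) NA_integer_)
    cells$zone[i] <- z
    if (is.na(z)) cells$kept[i] <- FALSE
  }
  list(cells = cells,
       tallies = zone_tally(cells[cells$kept & !is.na(cells$zone), ,
                                  drop = FALSE]))
}

#' Trajectory CSV round trip
#'
#' Columns: `cell_id, frame, t_s, locus_x, locus_y, nuc_x, nuc_y`.
#'
#' @param trajs A list of [trajectory()] objects (writer) / CSV path (reader).
#' @param path CSV path.
#' @return `write_trajectories_csv` returns `path` invisibly;
#'   `read_trajectories_csv` a list of `Trajectory` objects.
#' @export
write_trajectories_csv <- function(trajs, path) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  tab <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    id <- if (is.na(tr$cell_id)) sprintf("traj_%03d", i) else tr$cell_id
    data.frame(cell_id = id, frame = seq_along(tr$t_s) - 1L, t_s = tr$t_s,
               locus_x = tr$locus[, 1], locus_y = tr$locus[, 2],
               nuc_x = tr$nucleus[, 1], nuc_y = tr$nucleus[, 2])
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    trajectory(d$t_s, cbind(d$locus_x, d$locus_y), cbind(d$nuc_x, d$nuc_y),
               cell_id = d$cell_id[1])
  })
}

#' Fluctuation-experiment CSV round trip
#'
#' Columns: `culture_id, mutant_count, cells_plated, dilution`.
#'
#' @param sim A [simulate_fluctuation()] result or a list with `counts`,
#'   `N_t`, optionally `dilution`.
#' @param path CSV path.
#' @return Writer: `path` invisibly; reader: list with `counts`, `N_t`,
#'   `dilution`.
#' @export
write_fluctuation_csv <- function(sim, path) {
  dl <- if (!is.null(sim$dilution)) sim$dilution else 1
  tab <- data.frame(culture_id = seq_along(sim$counts),
                    mutant_count = sim$counts,
                    cells_plated = sim$N_t, dilution = dl)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluctuation_csv
#' @export
read_fluctuation_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(counts = as.integer(tab$mutant_count),
       N_t = tab$cells_plated[1], dilution = tab$dilution[1])
}

#' Write zone tallies as CSV
#'
#' @param tallies A [zone_tally()] data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tallies_csv <- function(tallies, path) {
  utils::write.csv(as.data.frame(tallies), path, row.names = FALSE)
  invisible(path)
}
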