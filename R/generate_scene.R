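#' Simulate the ground truth of an is-PLA acquisition
#'
#' Draws the object-level ground truth for a multi-field acquisition:
#' interphase nuclei (round, moderate DAPI intensity), mitotic chromosome
#' masses (brighter DAPI, irregular unions of 2-4 ellipse lobes, hence lower
#' circularity), one spindle per mitotic cell (bright compact ellipse in the
#' tubulin channel, axis perpendicular to the metaphase plate), and PLA
#' puncta. Control-condition puncta in mitotic cells are placed 60% on the
#' spindle, 25% at the chromosome periphery and 15% in the cytoplasm;
#' interphase cells carry a low nuclear puncta rate. Under the importazole
#' condition each punctum is kept with probability
#' `1 / ipz_puncta_fold_reduction`, so the expected per-cell puncta count
#' (and hence expected PLA sum intensity) is reduced by exactly the
#' configured fold while placement is unchanged.
#'
#' Cells are placed by rejection sampling with a minimum centre separation;
#' if a field cannot accommodate the requested number of cells the function
#' fails with an explicit placement error rather than silently truncating.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `ground_truth_scene` with elements `cells`,
#'   `objects` (data frame plus a parallel `shapes` list indexed by
#'   `object_id`), `puncta`, `condition`, `params` and `seed`.
#' @export
simulate_ground_truth <- function(params) {
  validate_scene_params(params)
  set.seed(params$rng_seed)
  g <- params$geometry; it <- params$intensity
  W <- params$image_size_px[1]; H <- params$image_size_px[2]
  zmid <- (params$z_planes + 1) / 2

  cells <- list(); objects <- list(); puncta <- list(); shapes <- list()
  cell_id <- 0L; object_id <- 0L

  for (field in seq_len(params$field_grid_count)) {
    n_cells <- if (params$cells_per_field[1] == params$cells_per_field[2]) {
      params$cells_per_field[1]
    } else sample(params$cells_per_field[1]:params$cells_per_field[2], 1L)
    if (n_cells == 0L) next
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, radius
    for (i in seq_len(n_cells)) {
      mitotic <- stats::runif(1) < params$mitotic_fraction
      ## placement footprint: the DAPI extent of the cell (lobed chromosome
      ## masses spread to ~1.8x the base lobe radius); spindles may graze a
      ## neighbour's cytoplasm, as in real fields
      r_eff <- if (mitotic) {
        1.8 * stats::rnorm(1, g$chromosome_radius_px_mean, g$chromosome_radius_px_sd)
      } else stats::rnorm(1, g$nucleus_radius_px_mean, g$nucleus_radius_px_sd)
      r_eff <- max(6, r_eff)
      margin <- r_eff + 3
      if (2 * margin >= min(W, H)) {
        stop("placement failure: image of ", W, "x", H,
             " px is too small for an object of radius ", round(r_eff), " px")
      }
      ok <- FALSE
      for (attempt in seq_len(400L)) {
        cx <- stats::runif(1, margin, W - margin)
        cy <- stats::runif(1, margin, H - margin)
        if (nrow(placed) == 0L ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + r_eff + g$min_separation_px)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("placement failure: could not place ", n_cells, " cells in a ",
             W, "x", H, " px field; reduce cells_per_field or enlarge the image")
      }
      placed <- rbind(placed, c(cx, cy, r_eff))
      cell_id <- cell_id + 1L
      theta <- stats::runif(1, 0, pi)
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = cell_id, field = field,
        class = if (mitotic) "mitotic" else "interphase",
        cx = cx, cy = cy)

      if (!mitotic) {
        a <- max(8, stats::rnorm(1, g$nucleus_radius_px_mean, g$nucleus_radius_px_sd))
        b <- a * stats::runif(1, g$nucleus_axis_ratio[1], g$nucleus_axis_ratio[2])
        shp <- list(type = "ellipse",
                    parts = list(list(cx = cx, cy = cy, a = a, b = b, theta = theta)))
        object_id <- object_id + 1L
        ac <- shape_area_circularity(shp)
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = object_id, cell_id = cell_id, field = field,
          class = "interphase_nucleus", channel = "DAPI",
          cx = cx, cy = cy,
          peak_intensity = stats::rlnorm(1, it$interphase_dapi_peak_meanlog,
                                         it$interphase_dapi_peak_sdlog),
          area_px = ac["area"], circularity = ac["circularity"])
        shapes[[object_id]] <- shp
        nucleus_ellipse <- shp$parts[[1]]
        ## interphase nuclear puncta (basal importin-partner interactions)
        n_p <- stats::rpois(1, it$puncta_rate_interphase)
        if (n_p > 0L) {
          pos <- runif_in_ellipse(n_p, nucleus_ellipse)
          puncta[[length(puncta) + 1L]] <- data.frame(
            cell_id = cell_id, field = field,
            x = pos[, "x"], y = pos[, "y"],
            z = pmin(params$z_planes, pmax(1, round(zmid + stats::rnorm(n_p, 0, 1)))),
            integrated_intensity = stats::rlnorm(n_p, it$puncta_meanlog, it$puncta_sdlog),
            compartment = "nucleus")
        }
      } else {
        ## chromosome mass: union of lobes spread along the metaphase plate
        a0 <- max(8, stats::rnorm(1, g$chromosome_radius_px_mean, g$chromosome_radius_px_sd))
        b0 <- a0 * stats::runif(1, g$chromosome_axis_ratio[1], g$chromosome_axis_ratio[2])
        k <- sample(g$chromosome_lobes[1]:g$chromosome_lobes[2], 1L)
        parts <- list(list(cx = cx, cy = cy, a = a0, b = b0, theta = theta))
        for (j in seq_len(k - 1L)) {
          t_off <- stats::runif(1, 0.6, 1.1) * a0 * sample(c(-1, 1), 1L)
          p_off <- stats::runif(1, -0.45, 0.45) * b0
          s <- stats::runif(1, 0.5, 0.8)
          parts[[length(parts) + 1L]] <- list(
            cx = cx + t_off * cos(theta) - p_off * sin(theta),
            cy = cy + t_off * sin(theta) + p_off * cos(theta),
            a = a0 * s, b = b0 * s,
            theta = theta + stats::runif(1, -0.4, 0.4))
        }
        chr_shape <- list(type = "multi_ellipse", parts = parts)
        object_id <- object_id + 1L
        chr_id <- object_id
        ac <- shape_area_circularity(chr_shape)
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = chr_id, cell_id = cell_id, field = field,
          class = "mitotic_chromosomes", channel = "DAPI",
          cx = cx, cy = cy,
          peak_intensity = stats::rlnorm(1, it$mitotic_dapi_peak_meanlog,
                                         it$mitotic_dapi_peak_sdlog),
          area_px = ac["area"], circularity = ac["circularity"])
        shapes[[chr_id]] <- chr_shape

        ## spindle: axis perpendicular to the metaphase plate
        sa <- max(10, stats::rnorm(1, g$spindle_radius_px_mean, g$spindle_radius_px_sd))
        sb <- sa * stats::runif(1, g$spindle_axis_ratio[1], g$spindle_axis_ratio[2])
        sp_theta <- theta + pi / 2
        sp_shape <- list(type = "ellipse",
                         parts = list(list(cx = cx, cy = cy, a = sa, b = sb,
                                           theta = sp_theta)))
        object_id <- object_id + 1L
        ac <- shape_area_circularity(sp_shape)
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = object_id, cell_id = cell_id, field = field,
          class = "spindle", channel = "FITC",
          cx = cx, cy = cy,
          peak_intensity = stats::rlnorm(1, it$spindle_fitc_peak_meanlog,
                                         it$spindle_fitc_peak_sdlog),
          area_px = ac["area"], circularity = ac["circularity"])
        shapes[[object_id]] <- sp_shape

        ## PLA puncta for the mitotic cell
        n_p <- stats::rpois(1, it$puncta_rate_mitotic)
        if (n_p > 0L) {
          comp <- sample(c("spindle", "chromosome_periphery", "cytoplasm"),
                         n_p, replace = TRUE, prob = c(0.60, 0.25, 0.15))
          pos <- matrix(0, n_p, 2, dimnames = list(NULL, c("x", "y")))
          sp_e <- sp_shape$parts[[1]]; chr_e <- parts[[1]]
          for (ci in seq_len(n_p)) {
            pos[ci, ] <- switch(comp[ci],
              spindle = runif_in_ellipse(1, sp_e),
              chromosome_periphery = runif_on_ellipse_rim(1, chr_e),
              cytoplasm = {
                phi <- stats::runif(1, 0, 2 * pi)
                rr <- stats::runif(1, 1.05, 1.5) * sa
                c(cx + rr * cos(phi), cy + rr * sin(phi))
              })
          }
          pos[, 1] <- pmin(W - 2, pmax(2, pos[, 1]))
          pos[, 2] <- pmin(H - 2, pmax(2, pos[, 2]))
          puncta[[length(puncta) + 1L]] <- data.frame(
            cell_id = cell_id, field = field,
            x = pos[, 1], y = pos[, 2],
            z = pmin(params$z_planes, pmax(1, round(zmid + stats::rnorm(n_p, 0, 1.5)))),
            integrated_intensity = stats::rlnorm(n_p, it$puncta_meanlog, it$puncta_sdlog),
            compartment = comp)
        }
      }
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  cells_df <- bind(cells, data.frame(cell_id = integer(), field = integer(),
                                     class = character(), cx = numeric(), cy = numeric()))
  objects_df <- bind(objects, data.frame(
    object_id = integer(), cell_id = integer(), field = integer(),
    class = character(), channel = character(), cx = numeric(), cy = numeric(),
    peak_intensity = numeric(), area_px = numeric(), circularity = numeric()))
  puncta_df <- bind(puncta, data.frame(
    cell_id = integer(), field = integer(), x = numeric(), y = numeric(),
    z = integer(), integrated_intensity = numeric(), compartment = character()))
  rownames(objects_df) <- rownames(puncta_df) <- rownames(cells_df) <- NULL

  ## importazole: thin puncta, keeping placement
  if (params$condition == "IPZ" && nrow(puncta_df) > 0L) {
    keep <- stats::runif(nrow(puncta_df)) < 1 / params$ipz_puncta_fold_reduction
    puncta_df <- puncta_df[keep, , drop = FALSE]
    rownames(puncta_df) <- NULL
  }
  if (nrow(puncta_df)) puncta_df$punctum_id <- seq_len(nrow(puncta_df))

  structure(list(cells = cells_df, objects = objects_df, shapes = shapes,
                 puncta = puncta_df, condition = params$condition,
                 params = params, seed = params$rng_seed,
                 schema_version = "1.0"),
            class = "ground_truth_scene")
}

#' Generate a ground-truthed synthetic acquisition
#'
#' Runs [simulate_ground_truth()] and [render_acquisition()] with the same
#' parameters: the one-call entry point of the simulator. Identical
#' parameters and seed give bit-identical scenes and stacks.
#'
#' @param params A [scene_params()] object.
#' @return List with elements `scene` (a `ground_truth_scene`) and `stack`
#'   (an `image_stack`).
#' @export
generate_scene <- function(params) {
  scene <- simulate_ground_truth(params)
  stack <- render_acquisition(scene, params)
  list(scene = scene, stack = stack)
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("ground_truth_scene:", nrow(x$cells), "cells (",
      sum(x$cells$class == "mitotic"), "mitotic ) in",
      x$params$field_grid_count, "fields;",
      nrow(x$puncta), "puncta; condition", x$condition, "\n")
  invisible(x)
}

## membership test against the analytic truth shape of one object
truth_object_contains <- function(scene, object_id, x, y) {
  shape_contains(scene$shapes[[object_id]], x, y)
}

#' Write / read ground truth as JSON
#'
#' The scene's object list, shapes and puncta are serialised to a versioned
#' JSON document so a rendered acquisition can be evaluated later without
#' re-running the simulator.
#'
#' @param scene A `ground_truth_scene`.
#' @param path Output path.
#' @return `path`, invisibly (`write_scene_json`); a `ground_truth_scene`
#'   (`read_scene_json`).
#' @export
write_scene_json <- function(scene, path) {
  x <- list(schema_version = scene$schema_version,
            condition = scene$condition, seed = scene$seed,
            cells = scene$cells, objects = scene$objects,
            shapes = scene$shapes, puncta = scene$puncta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  ## shapes hold ragged nested lists: reload without simplification
  raw <- jsonlite::read_json(path)
  shapes <- lapply(raw$shapes, function(s) {
    list(type = s$type,
         parts = lapply(s$parts, function(p) {
           list(cx = as.numeric(p$cx), cy = as.numeric(p$cy),
                a = as.numeric(p$a), b = as.numeric(p$b),
                theta = as.numeric(p$theta))
         }))
  })
  structure(list(cells = as.data.frame(x$cells), objects = as.data.frame(x$objects),
                 shapes = shapes, puncta = as.data.frame(x$puncta),
                 condition = x$condition, params = NULL, seed = x$seed,
                 schema_version = x$schema_version),
            class = "ground_truth_scene")
}
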