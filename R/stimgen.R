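#' Grid specification for ungrouped arrays
#'
#' Describes the virtual square area used for ungrouped stimuli: a tiling of
#' equally spaced cells, minus a central exclusion rectangle around fixation
#' where no item may appear. All dimensions are degrees of visual angle;
#' fixation is at the origin, x rightward, y upward. With the defaults
#' (6 x 6 deg area, 0.54 deg cells, 2.73 x 1.64 deg exclusion) the grid has
#' 106 usable positions.
#'
#' @param area_width,area_height Extent of the stimulus area (deg).
#' @param cell_size Pitch of the square grid cells (deg).
#' @param exclusion_width,exclusion_height Size of the central zone, centred
#'   on fixation, whose cells are removed (deg). May be 0.
#' @param item_size Side of the square items (deg); metadata only.
#' @return An object of class `grid_spec`.
#' @seealso [build_ungrouped_grid()], [sample_ungrouped()]
#' @export
grid_spec <- function(area_width = 6, area_height = 6, cell_size = 0.54,
                      exclusion_width = 2.73, exclusion_height = 1.64,
                      item_size = 0.4) {
  if (area_width <= 0 || area_height <= 0 || cell_size <= 0 || item_size <= 0)
    stop("grid dimensions must be positive", call. = FALSE)
  if (exclusion_width < 0 || exclusion_height < 0)
    stop("exclusion dimensions must be non-negative", call. = FALSE)
  if (exclusion_width > area_width || exclusion_height > area_height)
    stop("exclusion zone must fit inside the stimulus area", call. = FALSE)
  structure(
    list(area_width = area_width, area_height = area_height,
         cell_size = cell_size, exclusion_width = exclusion_width,
         exclusion_height = exclusion_height, item_size = item_size),
    class = "grid_spec"
  )
}

#' Quadrant specification for grouped arrays
#'
#' Grouped stimuli live in four rectangular quadrants, one per visual-field
#' quadrant, centred at `eccentricity` degrees from fixation along the
#' diagonals. Each quadrant holds a `n_cols` x `n_rows` lattice of item
#' slots (12 by default).
#'
#' @param quadrant_width,quadrant_height Quadrant extent (deg).
#' @param eccentricity Distance from fixation to each quadrant centre (deg).
#' @param n_cols,n_rows Slot lattice within a quadrant.
#' @return An object of class `quadrant_spec`.
#' @seealso [sample_grouped()], [quadrant_slots()]
#' @export
quadrant_spec <- function(quadrant_width = 1.64, quadrant_height = 2.2,
                          eccentricity = 3, n_cols = 3, n_rows = 4) {
  if (quadrant_width <= 0 || quadrant_height <= 0 || eccentricity <= 0)
    stop("quadrant dimensions must be positive", call. = FALSE)
  if (n_cols < 1 || n_rows < 1)
    stop("slot lattice must have at least one row and column", call. = FALSE)
  structure(
    list(quadrant_width = quadrant_width, quadrant_height = quadrant_height,
         eccentricity = eccentricity, n_cols = n_cols, n_rows = n_rows,
         slots_per_quadrant = n_cols * n_rows),
    class = "quadrant_spec"
  )
}

#' Enumerate the usable grid positions for ungrouped stimuli
#'
#' Tiles the stimulus area with as many whole cells as fit per axis, centred
#' on fixation, and removes cells whose centres fall strictly inside the
#' central exclusion rectangle. Deterministic for a given spec.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `x`, `y` (cell centres, deg).
#' @examples
#' nrow(build_ungrouped_grid()) # 106
#' @export
build_ungrouped_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  nx <- floor(spec$area_width / spec$cell_size + 1e-9)
  ny <- floor(spec$area_height / spec$cell_size + 1e-9)
  cx <- (seq_len(nx) - (nx + 1) / 2) * spec$cell_size
  cy <- (seq_len(ny) - (ny + 1) / 2) * spec$cell_size
  grid <- tidyr::expand_grid(x = cx, y = cy)
  excluded <- abs(grid$x) < spec$exclusion_width / 2 &
    abs(grid$y) < spec$exclusion_height / 2
  grid[!excluded, ]
}

#' Enumerate the item slots of the four quadrants
#'
#' @param spec A [quadrant_spec()].
#' @return A tibble with columns `quadrant` (1 upper-right, 2 upper-left,
#'   3 lower-left, 4 lower-right), `slot`, `x`, `y`.
#' @export
quadrant_slots <- function(spec = quadrant_spec()) {
  stopifnot(inherits(spec, "quadrant_spec"))
  e <- spec$eccentricity / sqrt(2)
  centres <- tibble::tibble(
    quadrant = 1:4,
    qx = c(e, -e, -e, e),
    qy = c(e, e, -e, -e)
  )
  dx <- (seq_len(spec$n_cols) - (spec$n_cols + 1) / 2) *
    spec$quadrant_width / spec$n_cols
  dy <- (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) *
    spec$quadrant_height / spec$n_rows
  offsets <- tidyr::expand_grid(ox = dx, oy = dy)
  offsets$slot <- seq_len(nrow(offsets))
  out <- tidyr::expand_grid(centres, offsets)
  tibble::tibble(
    quadrant = out$quadrant,
    slot = out$slot,
    x = out$qx + out$ox,
    y = out$qy + out$oy
  )
}

# The printed subgroup decompositions: 3 per numerosity 5..16, in order.
.configurations <- list(
  `5`  = list(c(2, 2, 1), c(3, 2), c(1, 1, 1, 2)),
  `6`  = list(c(3, 3), c(2, 2, 2), c(3, 2, 1)),
  `7`  = list(c(3, 3, 1), c(2, 2, 2, 1), c(3, 2, 1, 1)),
  `8`  = list(c(3, 3, 2), c(2, 2, 2, 2), c(4, 4)),
  `9`  = list(c(4, 3, 2), c(4, 4, 1), c(3, 3, 3)),
  `10` = list(c(3, 3, 3, 1), c(4, 4, 2), c(2, 2, 2, 4)),
  `11` = list(c(4, 4, 2, 1), c(3, 3, 3, 2), c(3, 4, 3, 1)),
  `12` = list(c(3, 3, 3, 3), c(4, 4, 4), c(4, 2, 3, 3)),
  `13` = list(c(5, 5, 3), c(4, 4, 4, 1), c(4, 3, 4, 2)),
  `14` = list(c(4, 4, 3, 3), c(4, 4, 4, 2), c(3, 3, 3, 5)),
  `15` = list(c(4, 4, 4, 3), c(5, 4, 4, 2), c(5, 5, 4, 1)),
  `16` = list(c(4, 4, 4, 4), c(4, 4, 3, 5), c(5, 5, 4, 2))
)

#' The grouped-stimulus configuration table
#'
#' Each numerosity from 5 to 16 is decomposed into 2-4 subgroups of at most 5
#' items; three decompositions per numerosity, 36 in total. These are the
#' exact decompositions used in the experimental design; one block of grouped
#' trials presents each configuration once.
#'
#' @return A tibble with columns `numerosity`, `configuration` (label such
#'   as `"3,3,2"`), `sizes` (list column of integer vectors) and
#'   `n_subgroups`.
#' @examples
#' cfg <- configuration_table()
#' nrow(cfg) # 36
#' @export
configuration_table <- function() {
  num <- rep(as.integer(names(.configurations)), each = 3L)
  sizes <- unlist(.configurations, recursive = FALSE, use.names = FALSE)
  tibble::tibble(
    numerosity = num,
    configuration = vapply(sizes, paste, character(1), collapse = ","),
    sizes = lapply(sizes, as.integer),
    n_subgroups = lengths(sizes)
  )
}

#' Sample an ungrouped stimulus array
#'
#' Draws `n` item positions uniformly without replacement from the usable
#' grid positions.
#'
#' @param n Numerosity (number of items).
#' @param spec A [grid_spec()].
#' @param seed Optional integer seed; when supplied the array is reproducible.
#' @return A `stimulus_array` object: list with `arrangement`, `numerosity`,
#'   `positions` (tibble of `x`, `y`), `group` (all `NA` for ungrouped),
#'   `configuration` (`NULL`), `seed`.
#' @export
sample_ungrouped <- function(n, spec = grid_spec(), seed = NULL) {
  grid <- build_ungrouped_grid(spec)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (n > nrow(grid))
    stop(sprintf("n = %d exceeds the %d available grid positions",
                 n, nrow(grid)), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(grid), n)
  structure(
    list(arrangement = "ungrouped", numerosity = as.integer(n),
         positions = grid[idx, ], group = rep(NA_integer_, n),
         configuration = NULL, seed = seed),
    class = "stimulus_array"
  )
}

#' Sample a grouped stimulus array
#'
#' Each subgroup of the configuration is assigned to a distinct, randomly
#' chosen quadrant, then its item slots are drawn without replacement within
#' that quadrant.
#'
#' @param config An integer vector of subgroup sizes (e.g. `c(3, 3, 2)`), a
#'   configuration label such as `"3,3,2"`, or a single row of
#'   [configuration_table()].
#' @param spec A [quadrant_spec()].
#' @param seed Optional integer seed.
#' @return A `stimulus_array` object; `group` maps each item to its subgroup.
#' @export
sample_grouped <- function(config, spec = quadrant_spec(), seed = NULL) {
  sizes <- .as_sizes(config)
  if (length(sizes) > 4)
    stop("at most 4 subgroups are supported (one per quadrant)",
         call. = FALSE)
  if (length(sizes) < 1 || any(sizes < 1))
    stop("subgroup sizes must be positive", call. = FALSE)
  if (max(sizes) > spec$slots_per_quadrant)
    stop(sprintf("subgroup of %d items exceeds the %d slots per quadrant",
                 max(sizes), spec$slots_per_quadrant), call. = FALSE)
  slots <- quadrant_slots(spec)
  if (!is.null(seed)) set.seed(seed)
  quads <- sample.int(4, length(sizes))
  pos <- vector("list", length(sizes))
  for (g in seq_along(sizes)) {
    qs <- slots[slots$quadrant == quads[g], ]
    pos[[g]] <- qs[sample.int(nrow(qs), sizes[g]), c("x", "y")]
  }
  structure(
    list(arrangement = "grouped", numerosity = as.integer(sum(sizes)),
         positions = dplyr::bind_rows(pos),
         group = rep(seq_along(sizes), sizes),
         configuration = paste(sizes, collapse = ","), seed = seed),
    class = "stimulus_array"
  )
}

.as_sizes <- function(config) {
  if (is.data.frame(config)) {
    stopifnot(nrow(config) == 1, "sizes" %in% names(config))
    return(as.integer(config$sizes[[1]]))
  }
  if (is.character(config)) {
    stopifnot(length(config) == 1)
    return(as.integer(strsplit(config, ",", fixed = TRUE)[[1]]))
  }
  as.integer(config)
}

#' @export
print.stimulus_array <- function(x, ...) {
  cat(sprintf("<stimulus_array> %s, N = %d%s%s\n", x$arrangement,
              x$numerosity,
              if (!is.null(x$configuration))
                paste0(", configuration ", x$configuration) else "",
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  print(tibble::as_tibble(cbind(x$positions, group = x$group)), ...)
  invisible(x)
}

#' Export stimulus arrays as JSON
#'
#' Writes one record per array with arrangement, numerosity, configuration,
#' seed and item positions in degrees of visual angle.
#'
#' @param arrays A `stimulus_array` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_stimuli <- function(arrays, path) {
  if (inherits(arrays, "stimulus_array")) arrays <- list(arrays)
  recs <- lapply(arrays, function(a) {
    list(arrangement = a$arrangement, numerosity = a$numerosity,
         configuration = a$configuration, seed = a$seed,
         group = a$group, x = a$positions$x, y = a$positions$y)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
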