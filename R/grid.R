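KIND_LEVELS <- c("SMC", "ECM", "MONOCYTE")
KIND_SMC <- 1L
KIND_ECM <- 2L
KIND_MONOCYTE <- 3L

kind_code <- function(kind) {
  code <- match(toupper(kind), KIND_LEVELS)
  if (any(is.na(code))) {
    abort("`kind` must be one of \"SMC\", \"ECM\", \"MONOCYTE\".")
  }
  code
}

#' Construct a lattice element
#'
#' One occupant of the intimal lattice: a smooth muscle cell, an
#' extracellular-matrix element, or a monocyte. SMC carry two timers used
#' by the matrix-production schedule: the time of their last division
#' (hours; `NA` for a cell that has never divided) and the number of
#' scheduled matrix elements produced since that division (0-2).
#'
#' @param kind `"SMC"`, `"ECM"` or `"MONOCYTE"`.
#' @param last_division_time Hours of the last division (SMC only).
#' @param ecm_produced Scheduled ECM produced since the last division,
#'   0, 1 or 2 (SMC only).
#' @return A `vg_element` list.
#' @examples
#' vg_element("SMC")
#' @export
vg_element <- function(kind, last_division_time = NA_real_, ecm_produced = 0L) {
  code <- kind_code(kind)
  if (code != KIND_SMC) {
    last_division_time <- NA_real_
    ecm_produced <- NA_integer_
  } else if (!is.na(ecm_produced) && !ecm_produced %in% 0:2) {
    abort("`ecm_produced` must be 0, 1 or 2.")
  }
  structure(
    list(kind = KIND_LEVELS[code],
         last_division_time = last_division_time,
         ecm_produced = as.integer(ecm_produced)),
    class = "vg_element"
  )
}

new_vg_grid <- function(kind, last_div, ecm_n, element_size, next_id = 1L) {
  structure(
    list(kind = kind, last_div = last_div, ecm_n = ecm_n,
         element_size = element_size, next_id = as.integer(next_id)),
    class = "vg_grid"
  )
}

#' Initialize the intimal lattice
#'
#' Builds the starting configuration of the grid. Columns run along the
#' graft (longitudinal position); each column is a contiguous stack of
#' elements ordered from the outer boundary (row 1) toward the lumen (top
#' of the stack). Two modes are supported:
#'
#' * `"single_smc_1d"`: one column holding a single SMC, the baseline
#'   thickness of a non-diseased venous intima (requires `n_columns = 1`).
#' * `"mixed_layer_2d"`: one element per column, independently assigned
#'   SMC with probability `init_smc_fraction` (default 0.25) and ECM
#'   otherwise, emulating the single cell layer of the freshly implanted
#'   vein with a 1:3 cell-to-matrix ratio.
#'
#' @param n_columns Number of longitudinal columns (1 for 1-D mode).
#' @param mode `"mixed_layer_2d"` or `"single_smc_1d"`.
#' @param init_smc_fraction Probability that an initial element is SMC
#'   (2-D mode).
#' @param element_size Lattice pitch, micrometres.
#' @param seed Optional integer seed for the random initial assignment.
#' @return A `vg_grid` object.
#' @examples
#' g <- init_grid(10, mode = "mixed_layer_2d", seed = 1)
#' grid_heights(g)
#' @export
init_grid <- function(n_columns,
                      mode = c("mixed_layer_2d", "single_smc_1d"),
                      init_smc_fraction = 0.25,
                      element_size = 7,
                      seed = NULL) {
  mode <- match.arg(mode)
  if (n_columns < 1) abort("`n_columns` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "single_smc_1d") {
    if (n_columns != 1L) abort("1-D mode requires exactly one column.")
    kind <- list(KIND_SMC)
    last_div <- list(NA_real_)
    ecm_n <- list(0L)
    return(new_vg_grid(kind, last_div, ecm_n, element_size, next_id = 2L))
  }
  if (init_smc_fraction <= 0 || init_smc_fraction > 1) {
    abort("`init_smc_fraction` must lie in (0, 1].")
  }
  smc <- stats::runif(n_columns) < init_smc_fraction
  kind <- as.list(ifelse(smc, KIND_SMC, KIND_ECM))
  last_div <- lapply(smc, function(s) if (s) NA_real_ else NA_real_)
  ecm_n <- lapply(smc, function(s) if (s) 0L else NA_integer_)
  new_vg_grid(kind, last_div, ecm_n, element_size, next_id = n_columns + 1L)
}

#' @rdname init_grid
#' @param grid A `vg_grid`.
#' @return `grid_heights()`: integer vector of stack heights per column.
#' @export
grid_heights <- function(grid) {
  vapply(grid$kind, length, integer(1))
}

#' Count elements of the grid
#'
#' @param grid A `vg_grid`.
#' @param kind Optional element kind to count; `NULL` counts everything.
#' @return Integer count.
#' @export
n_elements <- function(grid, kind = NULL) {
  if (is.null(kind)) return(sum(grid_heights(grid)))
  code <- kind_code(kind)
  sum(vapply(grid$kind, function(k) sum(k == code), integer(1)))
}

check_position <- function(grid, column, row, allow_top = FALSE) {
  h <- grid_heights(grid)
  if (column < 1 || column > length(h)) abort("`column` out of range.")
  top <- h[column] + if (allow_top) 1L else 0L
  if (row < 1 || row > top) {
    abort(sprintf("`row` %d out of range for column %d (height %d).",
                  row, column, h[column]))
  }
  invisible(TRUE)
}

#' Insert an element with lumen-ward displacement
#'
#' Places `element` at `(column, row)`; all elements previously at that row
#' or above are displaced one position toward the lumen, reproducing the
#' fixed outer boundary and inward thickening of the remodeling wall.
#' `row = height + 1` appends at the lumen surface without displacement.
#'
#' @param grid A `vg_grid`.
#' @param column Column index (1-based).
#' @param row Row index, 1 (outer boundary) to height + 1 (lumen surface).
#' @param element A [vg_element()].
#' @return The modified grid.
#' @examples
#' g <- init_grid(1, mode = "single_smc_1d")
#' g <- insert_element(g, 1, 1, vg_element("ECM"))
#' grid_heights(g)  # 2
#' @export
insert_element <- function(grid, column, row, element) {
  if (!inherits(element, "vg_element")) abort("`element` must be a `vg_element`.")
  check_position(grid, column, row, allow_top = TRUE)
  code <- kind_code(element$kind)
  grid$kind[[column]] <- append(grid$kind[[column]], code, after = row - 1L)
  grid$last_div[[column]] <- append(grid$last_div[[column]],
                                    element$last_division_time, after = row - 1L)
  grid$ecm_n[[column]] <- append(grid$ecm_n[[column]],
                                 element$ecm_produced, after = row - 1L)
  grid$next_id <- grid$next_id + 1L
  grid
}

#' Remove an element with outward collapse
#'
#' Removes the element at `(column, row)`; elements above it shift one
#' position outward (downward) so the stack stays contiguous. The removed
#' element is attached to the result as attribute `"removed"`.
#'
#' @inheritParams insert_element
#' @return The modified grid, with the removed [vg_element()] in
#'   `attr(, "removed")`.
#' @export
remove_element <- function(grid, column, row) {
  check_position(grid, column, row)
  removed <- vg_element(KIND_LEVELS[grid$kind[[column]][row]],
                        grid$last_div[[column]][row],
                        grid$ecm_n[[column]][row])
  grid$kind[[column]] <- grid$kind[[column]][-row]
  grid$last_div[[column]] <- grid$last_div[[column]][-row]
  grid$ecm_n[[column]] <- grid$ecm_n[[column]][-row]
  attr(grid, "removed") <- removed
  grid
}

#' Remove the matrix elements nearest to an apoptotic cell
#'
#' Implements matrix degradation at cell death: up to `count` ECM elements
#' with the smallest Euclidean distance (in grid-index space, over the
#' whole grid) from `(column, row)` are removed with outward collapse.
#' Distance ties are broken by a uniform random draw; if fewer than
#' `count` ECM exist, all of them are removed with a warning.
#'
#' @inheritParams insert_element
#' @param count Number of ECM elements to remove (default 4).
#' @return The modified grid; `attr(, "removed_positions")` is a tibble of
#'   the removed positions (`column`, `row`, `distance`, pre-removal
#'   coordinates).
#' @export
remove_nearest_ecm <- function(grid, column, row, count = 4L) {
  h <- grid_heights(grid)
  if (column < 1 || column > length(h)) abort("`column` out of range.")
  ecm <- purrr::map_dfr(seq_along(grid$kind), function(cc) {
    rows <- which(grid$kind[[cc]] == KIND_ECM)
    tibble::tibble(column = rep.int(cc, length(rows)), row = rows)
  })
  if (nrow(ecm) == 0L) {
    warn("No ECM elements available for degradation.")
    attr(grid, "removed_positions") <-
      tibble::tibble(column = integer(), row = integer(), distance = numeric())
    return(grid)
  }
  if (nrow(ecm) < count) {
    warn(sprintf("Only %d ECM element(s) available; removing all of them.", nrow(ecm)))
  }
  d <- sqrt((ecm$column - column)^2 + (ecm$row - row)^2)
  ord <- order(d, stats::runif(length(d)))  # random tie-break
  take <- ecm[head(ord, count), ]
  take$distance <- d[head(ord, count)]
  # remove per column from the top down so earlier removals cannot shift
  # the rows of later ones
  doomed <- take[order(take$column, -take$row), ]
  for (i in seq_len(nrow(doomed))) {
    grid <- remove_element(grid, doomed$column[i], doomed$row[i])
  }
  attr(grid, "removed") <- NULL
  attr(grid, "removed_positions") <- tibble::as_tibble(take)
  grid
}

#' Redistribute elements between adjacent columns
#'
#' The smoothing rule of the two-dimensional algorithm: whenever two
#' adjacent columns differ in height by more than two elements, the top
#' (lumen-most) element of the taller column moves to the top of the
#' shorter one. Sweeps run left-to-right then right-to-left, repeated to a
#' fixed point, so the result is deterministic given the grid. On return
#' every adjacent pair differs by at most two elements; total element
#' count is conserved.
#'
#' @param grid A `vg_grid`.
#' @return The modified grid; `attr(, "moves")` is the number of element
#'   moves performed.
#' @examples
#' g <- init_grid(2, seed = 1)
#' for (i in 1:5) g <- insert_element(g, 1, 1, vg_element("ECM"))
#' grid_heights(redistribute(g))
#' @export
redistribute <- function(grid) {
  n <- length(grid$kind)
  moves <- 0L
  move_top <- function(from, to) {
    r <- length(grid$kind[[from]])
    el <- vg_element(KIND_LEVELS[grid$kind[[from]][r]],
                     grid$last_div[[from]][r], grid$ecm_n[[from]][r])
    grid <<- remove_element(grid, from, r)
    grid <<- insert_element(grid, to, length(grid$kind[[to]]) + 1L, el)
    grid$next_id <<- grid$next_id - 1L  # a move is not a new element
    moves <<- moves + 1L
  }
  if (n >= 2L) {
    repeat {
      before <- moves
      for (i in seq_len(n - 1L)) {                 # left-to-right
        while (abs(length(grid$kind[[i]]) - length(grid$kind[[i + 1L]])) > 2L) {
          if (length(grid$kind[[i]]) > length(grid$kind[[i + 1L]])) {
            move_top(i, i + 1L)
          } else move_top(i + 1L, i)
        }
      }
      for (i in rev(seq_len(n - 1L))) {            # right-to-left
        while (abs(length(grid$kind[[i]]) - length(grid$kind[[i + 1L]])) > 2L) {
          if (length(grid$kind[[i]]) > length(grid$kind[[i + 1L]])) {
            move_top(i, i + 1L)
          } else move_top(i + 1L, i)
        }
      }
      if (moves == before) break
    }
  }
  attr(grid, "removed") <- NULL
  attr(grid, "moves") <- moves
  grid
}

#' Center-based distances of an element from lumen and outer wall
#'
#' Distances are measured from the element's center: an element at row `r`
#' of a column of height `h` lies `(h - r + 0.5) * element_size` below the
#' lumen surface and `(r - 0.5) * element_size` above the outer boundary.
#' The two always sum to the column's intimal thickness.
#'
#' @inheritParams insert_element
#' @return Named numeric vector `c(d_lumen =, d_outer =)`, millimetres.
#' @export
element_distances <- function(grid, column, row) {
  check_position(grid, column, row)
  es_mm <- grid$element_size / 1000
  h <- length(grid$kind[[column]])
  c(d_lumen = (h - row + 0.5) * es_mm, d_outer = (row - 0.5) * es_mm)
}

#' @export
print.vg_grid <- function(x, ...) {
  h <- grid_heights(x)
  cat(sprintf("<vg_grid> %d column(s), %d element(s) (%d SMC, %d ECM, %d monocyte)\n",
              length(h), sum(h), n_elements(x, "SMC"), n_elements(x, "ECM"),
              n_elements(x, "MONOCYTE")))
  cat(sprintf("  heights: min %d, median %s, max %d; element size %g um\n",
              if (length(h)) min(h) else 0L, format(stats::median(h)),
              if (length(h)) max(h) else 0L, x$element_size))
  invisible(x)
}

#' Tabular view of a grid
#'
#' @param x A `vg_grid`.
#' @param ... Unused.
#' @return A tibble with one row per element: `column`, `row` (1 = outer
#'   boundary), `kind`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.vg_grid <- function(x, ...) {
  purrr::map_dfr(seq_along(x$kind), function(cc) {
    k <- x$kind[[cc]]
    tibble::tibble(column = rep.int(cc, length(k)),
                   row = seq_along(k),
                   kind = KIND_LEVELS[k])
  })
}

#' Read and write grid snapshots as CSV
#'
#' The snapshot format has one row per element with columns
#' `column,row,kind` (`kind` in SMC/ECM/MONOCYTE) and round-trips exactly.
#' SMC production timers are runtime state and are not persisted.
#'
#' @param grid A `vg_grid`.
#' @param path File path.
#' @param element_size Lattice pitch for the reconstructed grid, um.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   returns a `vg_grid`.
#' @export
write_grid_csv <- function(grid, path) {
  readr::write_csv(as_tibble(grid), path)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, element_size = 7) {
  df <- readr::read_csv(path, col_types = readr::cols(
    column = readr::col_integer(), row = readr::col_integer(),
    kind = readr::col_character()
  ))
  if (nrow(df) == 0L) abort("Empty grid snapshot.")
  n_col <- max(df$column)
  code <- kind_code(df$kind)
  kind <- lapply(seq_len(n_col), function(cc) {
    sub <- df[df$column == cc, ]
    sub <- sub[order(sub$row), ]
    if (nrow(sub) && !identical(sub$row, seq_len(nrow(sub)))) {
      abort(sprintf("Column %d of the snapshot has holes.", cc))
    }
    code[df$column == cc][order(df$row[df$column == cc])]
  })
  last_div <- lapply(kind, function(k) ifelse(k == KIND_SMC, NA_real_, NA_real_))
  ecm_n <- lapply(kind, function(k) ifelse(k == KIND_SMC, 0L, NA_integer_))
  new_vg_grid(kind, last_div, ecm_n, element_size,
              next_id = sum(lengths(kind)) + 1L)
}
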