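dir_target_r <- function(i, j, k) {
  p <- as.integer((j - 1L) %% 2L == 1L) # 1 in shifted columns
  switch(k,
         c(i - 1L, j),           # up
         c(i + 1L, j),           # down
         c(i - 1L + p, j + 1L),  # right-up
         c(i + p, j + 1L),       # right-down
         c(i - 1L + p, j - 1L),  # left-up
         c(i + p, j - 1L))       # left-down
}

#' Eligible daughter placements around a mother cell
#'
#' A dividing mother may place its daughter at any of its six neighbor
#' sites that is either empty, or occupied by a neighbor cell that can be
#' displaced one further step along the same lattice direction into an
#' empty site (at most one level of displacement).
#'
#' @param occupancy 0/1 matrix of occupied sites (a partially grown grid).
#' @param mother length-2 vector `c(row, col)`, 1-based; must be occupied.
#' @return data.frame with one row per eligible placement: `row`, `col`
#'   (the daughter site), `displaced` (logical), and `push_row`, `push_col`
#'   (where the displaced occupant moves; `NA` when no displacement).
#' @export
eligible_sites <- function(occupancy, mother) {
  occupancy <- as.matrix(occupancy)
  mother <- as.integer(mother)
  nr <- nrow(occupancy); nc <- ncol(occupancy)
  if (mother[1] < 1L || mother[1] > nr || mother[2] < 1L || mother[2] > nc)
    stop("mother site outside the grid")
  if (occupancy[mother[1], mother[2]] != 1) stop("mother site must be occupied")
  inb <- function(s) s[1] >= 1L && s[1] <= nr && s[2] >= 1L && s[2] <= nc
  out <- list()
  for (k in 1:6) {
    t1 <- dir_target_r(mother[1], mother[2], k)
    if (!inb(t1)) next
    if (occupancy[t1[1], t1[2]] == 0) {
      out[[length(out) + 1L]] <- data.frame(
        row = t1[1], col = t1[2], displaced = FALSE,
        push_row = NA_integer_, push_col = NA_integer_)
    } else {
      t2 <- dir_target_r(t1[1], t1[2], k)
      if (inb(t2) && occupancy[t2[1], t2[2]] == 0) {
        out[[length(out) + 1L]] <- data.frame(
          row = t1[1], col = t1[2], displaced = TRUE,
          push_row = t2[1], push_col = t2[2])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      displaced = logical(0), push_row = integer(0),
                      push_col = integer(0)))
  do.call(rbind, out)
}
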