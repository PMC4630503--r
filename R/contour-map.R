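#' Create a contour map
#'
#' A contour map is a binary raster in which pixels equal to 1 lie on a
#' contour. Rows are indexed top to bottom, columns left to right, both
#' 1-based (R convention).
#'
#' @param grid A numeric or integer matrix; nonzero entries are contour
#'   pixels.
#' @param provenance Free-text tag recording where the map came from
#'   (generator name and parameters, or a file path).
#' @return An object of class `contour_map` with elements `grid`
#'   (integer 0/1 matrix) and `provenance`.
#' @examples
#' m <- contour_map(matrix(c(0, 1, 0, 1), 2, 2))
#' sum(m$grid)
#' @export
contour_map <- function(grid, provenance = "unspecified") {
  if (!is.matrix(grid)) abort("`grid` must be a matrix.")
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  structure(list(grid = g, provenance = as.character(provenance)[1]),
            class = "contour_map")
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("<contour_map> %d x %d, %d contour px, provenance: %s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$provenance))
  invisible(x)
}

#' Read and write contour maps
#'
#' Maps round-trip through two plain formats: 8-bit grayscale PNG (any
#' nonzero intensity is contour) and whitespace-delimited 0/1 text grids.
#' The format is chosen from the file extension (`.png` vs anything else).
#'
#' @param path File path.
#' @param map A `contour_map`.
#' @return `read_contour_map()` returns a `contour_map`;
#'   `write_contour_map()` returns `path` invisibly.
#' @export
read_contour_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    contour_map(img > 0, provenance = path)
  } else {
    g <- as.matrix(read.table(path))
    dimnames(g) <- NULL
    contour_map(g, provenance = path)
  }
}

#' @rdname read_contour_map
#' @export
write_contour_map <- function(map, path) {
  stopifnot(inherits(map, "contour_map"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(map$grid + 0, path)
  } else {
    write.table(map$grid, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Trace pixel chains in a binary contour map
#'
#' Partitions the contour pixels of a map into maximal 8-connected ordered
#' chains. Every contour pixel belongs to exactly one chain. At branch
#' points the walk continues into the neighbour whose unvisited reachable
#' set is largest (longest continuation first); ties are broken toward
#' 4-connected neighbours (so staircase corners stay in the chain), then by
#' lexicographic (row, column) order, so tracing is deterministic.
#'
#' @param map A `contour_map`.
#' @return A list of integer matrices, each `m x 2` (columns `row`, `col`),
#'   ordered along the chain. An empty map gives an empty list.
#' @examples
#' g <- matrix(0L, 9, 9); g[2:8, 5] <- 1L
#' length(trace_contours(contour_map(g)))
#' @export
trace_contours <- function(map) {
  stopifnot(inherits(map, "contour_map"))
  g <- map$grid
  px <- which(g == 1L, arr.ind = TRUE)
  if (nrow(px) == 0) return(list())
  nr <- nrow(g); nc <- ncol(g)
  key <- function(r, c) (c - 1L) * nr + r
  occupied <- logical(nr * nc)
  occupied[key(px[, 1], px[, 2])] <- TRUE
  visited <- logical(nr * nc)

  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]

  neighbours <- function(r, c) {
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    on <- occupied[key(rr, cc)] & !visited[key(rr, cc)]
    cbind(rr[on], cc[on])
  }

  # Size of the unvisited component reachable from (r, c): BFS.
  reach_size <- function(r, c) {
    seen <- new.env(hash = TRUE, size = 64L)
    q <- list(c(r, c)); assign(as.character(key(r, c)), TRUE, envir = seen)
    n <- 0L
    while (length(q)) {
      p <- q[[length(q)]]; q[[length(q)]] <- NULL
      n <- n + 1L
      nb <- neighbours(p[1], p[2])
      if (nrow(nb)) for (i in seq_len(nrow(nb))) {
        k <- as.character(key(nb[i, 1], nb[i, 2]))
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          q[[length(q) + 1L]] <- nb[i, ]
        }
      }
    }
    n
  }

  degree <- function(r, c) nrow(neighbours(r, c))

  # Walk from a start pixel, preferring the largest unvisited continuation.
  walk <- function(r, c) {
    path <- matrix(0L, 0, 2)
    repeat {
      visited[key(r, c)] <<- TRUE
      path <- rbind(path, c(r, c))
      nb <- neighbours(r, c)
      if (nrow(nb) == 0) break
      if (nrow(nb) == 1) {
        r <- nb[1, 1]; c <- nb[1, 2]
      } else {
        sizes <- vapply(seq_len(nrow(nb)),
                        function(i) reach_size(nb[i, 1], nb[i, 2]), integer(1))
        # ties (mutually adjacent candidates) favour the 4-connected
        # neighbour so staircase corner pixels are swept into the chain
        diag_step <- abs(nb[, 1] - r) + abs(nb[, 2] - c) == 2L
        ord <- order(-sizes, diag_step, nb[, 1], nb[, 2])
        r <- nb[ord[1], 1]; c <- nb[ord[1], 2]
      }
    }
    path
  }

  # Start at endpoints (degree 1) in lexicographic order, then any leftover
  # (closed loops / interior remnants), also lexicographic.
  chains <- list()
  ord <- order(px[, 1], px[, 2])
  px <- px[ord, , drop = FALSE]
  repeat {
    unv <- !visited[key(px[, 1], px[, 2])]
    if (!any(unv)) break
    cand <- px[unv, , drop = FALSE]
    degs <- vapply(seq_len(nrow(cand)),
                   function(i) degree(cand[i, 1], cand[i, 2]), integer(1))
    pick <- if (any(degs <= 1)) which(degs <= 1)[1] else 1L
    ch <- walk(cand[pick, 1], cand[pick, 2])
    colnames(ch) <- c("row", "col")
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}
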