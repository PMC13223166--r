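#' Anatomical atlas of the 14 lymph node zones
#'
#' The analysis classifies resected lymph nodes into 14 anatomical regions:
#' left/right common iliac (1, 2), left/right external iliac (3, 4),
#' left/right internal iliac (5, 6), left/right obturator (7, 8),
#' left/right superficial inguinal (9, 10), left/right para-aortic (11, 12),
#' presacral (13) and distant nodes such as mesenteric or supraclavicular
#' (14).  The atlas also carries a set of unordered zone pairs regarded as
#' anatomically plausible direct connections; pathway extraction discards
#' candidate routes between zones that are not adjacent in this sense.
#'
#' The default adjacency encodes, per side, the iliac chain
#' (external/internal -> common iliac, external -> internal), drainage from
#' the iliac chains into the obturator fossa, obturator -> inguinal and
#' obturator -> presacral spread, common iliac -> para-aortic and
#' common iliac -> presacral continuation, the contralateral pairs
#' (common iliac, external iliac, internal iliac, obturator, inguinal and
#' para-aortic left/right pairs), and connections from the common iliac and
#' para-aortic stations to the distant compartment.
#'
#' @param adjacency Optional replacement adjacency: a two-column matrix or
#'   data.frame of zone id pairs (order within a pair is irrelevant).
#' @return An object of class `zone_atlas`: a list with `zones` (data.frame
#'   with columns `id`, `name`, `side`) and `adjacency` (two-column integer
#'   matrix of unordered pairs, stored with the smaller id first).
#' @examples
#' atlas <- zone_atlas()
#' atlas$zones
#' zone_adjacent(atlas, 3, 5)
#' @export
zone_atlas <- function(adjacency = NULL) {
  zones <- data.frame(
    id = 1:14,
    name = c(
      "left common iliac", "right common iliac",
      "left external iliac", "right external iliac",
      "left internal iliac", "right internal iliac",
      "left obturator", "right obturator",
      "left superficial inguinal", "right superficial inguinal",
      "left para-aortic", "right para-aortic",
      "presacral", "distant"
    ),
    side = c(
      "left", "right", "left", "right", "left", "right", "left", "right",
      "left", "right", "left", "right", "midline", "distant"
    ),
    stringsAsFactors = FALSE
  )
  if (is.null(adjacency)) {
    adjacency <- rbind(
      # left-sided chain
      c(1, 3), c(1, 5), c(3, 5), c(3, 7), c(5, 7), c(7, 9),
      c(7, 13), c(1, 11), c(1, 13),
      # right-sided chain
      c(2, 4), c(2, 6), c(4, 6), c(4, 8), c(6, 8), c(8, 10),
      c(8, 13), c(2, 12), c(2, 13),
      # contralateral pairs
      c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10), c(11, 12),
      # connections into the distant compartment
      c(11, 14), c(12, 14), c(1, 14), c(2, 14)
    )
  }
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) {
    stop("adjacency must have two columns (zone id pairs)")
  }
  storage.mode(adjacency) <- "integer"
  if (any(!adjacency %in% zones$id)) {
    stop("adjacency refers to zone ids outside 1..14")
  }
  if (any(adjacency[, 1] == adjacency[, 2])) {
    stop("adjacency may not pair a zone with itself")
  }
  adjacency <- t(apply(adjacency, 1L, sort))
  adjacency <- unique(adjacency)
  dimnames(adjacency) <- NULL
  structure(list(zones = zones, adjacency = adjacency), class = "zone_atlas")
}

#' Test anatomical adjacency of two zones
#'
#' @param atlas A [zone_atlas()].
#' @param a,b Zone ids (1-14).
#' @return Logical: is the unordered pair in the atlas adjacency?
#' @export
zone_adjacent <- function(atlas, a, b) {
  stopifnot(inherits(atlas, "zone_atlas"))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi) %in% paste(atlas$adjacency[, 1], atlas$adjacency[, 2])
}

#' Zone variable names used in cohort tables and network nodes
#'
#' Zero-padded so that lexicographic order equals numeric zone order.
#'
#' @param ids Zone ids (default all 14).
#' @return Character vector like `"zone_01"`.
#' @export
zone_names <- function(ids = 1:14) {
  sprintf("zone_%02d", ids)
}

#' Map zone variable names back to integer ids
#'
#' @param x Character vector of zone variable names (`"zone_07"`).
#' @return Integer zone ids.
#' @export
zone_ids <- function(x) {
  as.integer(sub("^zone_", "", x))
}

#' @export
print.zone_atlas <- function(x, ...) {
  cat("Zone atlas: 14 lymph node regions,",
      nrow(x$adjacency), "plausible connections\n")
  print(x$zones, row.names = FALSE)
  invisible(x)
}
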