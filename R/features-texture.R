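# Texture features: gray-level co-occurrence (GLCM), size-zone (GLZLM) and
# run-length (GLRLM) matrices on a quantized ROI grid (NA = background).

# direction offsets as (drow, dcol): 0 deg = horizontal, 90 = vertical,
# 45 / 135 = the two diagonals
glcm_offsets <- function(directions = c("0", "45", "90", "135")) {
  all <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
              `90` = c(1L, 0L), `135` = c(1L, 1L))
  if (!all(directions %in% names(all))) {
    abort("directions must be among 0, 45, 90, 135",
          class = "stirq_radiomics_error")
  }
  all[directions]
}

# symmetric normalized GLCM averaged over directions (distance 1)
glcm_matrix <- function(q, directions = c("0", "45", "90", "135")) {
  grid <- q$grid
  G <- q$G
  offs <- glcm_offsets(directions)
  nr <- nrow(grid); nc <- ncol(grid)
  mats <- list()
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- grid[r1, c1, drop = FALSE]
    b <- grid[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    i <- a[keep]; j <- b[keep]
    # count each pair in both orders (symmetric GLCM)
    counts <- tabulate(c(i + (j - 1L) * G, j + (i - 1L) * G), nbins = G * G)
    m <- matrix(counts, G, G)
    mats[[length(mats) + 1]] <- m / sum(m)
  }
  if (length(mats) == 0) {
    abort("GLCM undefined: no valid neighbor pair in the ROI",
          class = "stirq_radiomics_error")
  }
  Reduce(`+`, mats) / length(mats)
}

#' Gray-level co-occurrence features
#'
#' Builds symmetric distance-1 GLCMs for the requested 2D directions,
#' normalizes each to sum 1, averages the matrices, and emits seven scalar
#' features (homogeneity, energy, contrast, correlation, entropies,
#' dissimilarity) with the standard formulas. Correlation is defined as 0
#' when the marginal variance vanishes (single-level ROI).
#'
#' @param q a [quantize_roi()] result.
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return Named numeric vector of length 7 (`GLCM_*`).
#' @export
glcm_features <- function(q, directions = c("0", "45", "90", "135")) {
  P <- glcm_matrix(q, directions)
  G <- nrow(P)
  i <- matrix(1:G, G, G)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  pos <- P[P > 0]
  corr <- if (var_i > 0 && var_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  } else 0
  c(
    GLCM_Homogeneity = sum(P / (1 + abs(i - j))),
    GLCM_Energy = sum(P^2),
    GLCM_Contrast = sum(P * (i - j)^2),
    GLCM_Correlation = corr,
    GLCM_Entropy_log10 = -sum(pos * log10(pos)),
    GLCM_Entropy_log2 = -sum(pos * log2(pos)),
    GLCM_Dissimilarity = sum(P * abs(i - j))
  )
}

# label 8-connected flat zones (same gray level) via the adjacency graph
glzlm_matrix <- function(q) {
  grid <- q$grid
  nr <- nrow(grid); nc <- ncol(grid)
  cells <- which(!is.na(grid))
  if (length(cells) == 0) {
    abort("empty ROI", class = "stirq_radiomics_error")
  }
  edge_list <- list()
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- grid[r1, c1, drop = FALSE]
    b <- grid[r1 + dr, c1 + dc, drop = FALSE]
    ia <- outer(r1, (c1 - 1L) * nr, "+")
    ib <- outer(r1 + dr, (c1 + dc - 1L) * nr, "+")
    keep <- !is.na(a) & !is.na(b) & a == b
    if (any(keep)) edge_list[[length(edge_list) + 1]] <- cbind(ia[keep], ib[keep])
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(edge_list) > 0) {
    edges <- do.call(rbind, edge_list)
    g <- igraph::add_edges(g, t(cbind(match(edges[, 1], cells),
                                      match(edges[, 2], cells))))
  }
  comp <- igraph::components(g)
  zone_level <- tapply(grid[cells], comp$membership, function(v) v[1])
  zone_size <- as.vector(comp$csize)
  Z <- max(zone_size)
  M <- matrix(0, q$G, Z)
  for (k in seq_along(zone_size)) {
    M[zone_level[k], zone_size[k]] <- M[zone_level[k], zone_size[k]] + 1
  }
  M
}

#' Gray-level size-zone features
#'
#' Flat zones are maximal 8-connected sets of equal gray level; the GLZLM
#' counts zones by level and size. Emits the eleven standard size-zone
#' scalars (SZE, LZE, LGZE, HGZE, the four joint emphases, GLNU, ZLNU, ZP).
#'
#' @param q a [quantize_roi()] result.
#' @return Named numeric vector of length 11 (`GLZLM_*`).
#' @export
glzlm_features <- function(q) {
  M <- glzlm_matrix(q)
  n_pixels <- sum(!is.na(q$grid))
  Ns <- sum(M)
  g <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  z <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  c(
    GLZLM_SZE = sum(M / z^2) / Ns,
    GLZLM_LZE = sum(M * z^2) / Ns,
    GLZLM_LGZE = sum(M / g^2) / Ns,
    GLZLM_HGZE = sum(M * g^2) / Ns,
    GLZLM_SZLGE = sum(M / (z^2 * g^2)) / Ns,
    GLZLM_SZHGE = sum(M * g^2 / z^2) / Ns,
    GLZLM_LZLGE = sum(M * z^2 / g^2) / Ns,
    GLZLM_LZHGE = sum(M * z^2 * g^2) / Ns,
    GLZLM_GLNU = sum(rowSums(M)^2) / Ns,
    GLZLM_ZLNU = sum(colSums(M)^2) / Ns,
    GLZLM_ZP = Ns / n_pixels
  )
}

# run-length matrix for one direction: maximal runs of equal level along the
# direction's scan lines (background breaks runs)
glrlm_matrix_dir <- function(grid, G, direction) {
  nr <- nrow(grid); nc <- ncol(grid)
  lines <- switch(direction,
    `0` = lapply(seq_len(nr), function(r) grid[r, ]),
    `90` = lapply(seq_len(nc), function(c) grid[, c]),
    `45` = split(grid[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))],
                 rep(seq_len(nc), each = nr) + rep(seq_len(nr), nc)),
    `135` = split(grid[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))],
                  rep(seq_len(nc), each = nr) - rep(seq_len(nr), nc))
  )
  max_len <- max(nr, nc)
  M <- matrix(0, G, max_len)
  for (line in lines) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    for (k in which(keep)) {
      M[r$values[k], r$lengths[k]] <- M[r$values[k], r$lengths[k]] + 1
    }
  }
  M
}

#' Gray-level run-length features
#'
#' Run-length matrices are built for the four 2D directions and averaged
#' (count matrices, element-wise); emits eight standard run-length scalars.
#'
#' @param q a [quantize_roi()] result.
#' @return Named numeric vector of length 8 (`GLRLM_*`).
#' @export
glrlm_features <- function(q) {
  grid <- q$grid
  n_pixels <- sum(!is.na(grid))
  if (n_pixels == 0) abort("empty ROI", class = "stirq_radiomics_error")
  dirs <- c("0", "45", "90", "135")
  mats <- lapply(dirs, function(d) glrlm_matrix_dir(grid, q$G, d))
  max_len <- max(vapply(mats, ncol, integer(1)))
  mats <- lapply(mats, function(m) {
    cbind(m, matrix(0, nrow(m), max_len - ncol(m)))
  })
  M <- Reduce(`+`, mats) / length(mats)
  Nr <- sum(M)
  g <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  l <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  c(
    GLRLM_SRE = sum(M / l^2) / Nr,
    GLRLM_LRE = sum(M * l^2) / Nr,
    GLRLM_LGRE = sum(M / g^2) / Nr,
    GLRLM_HGRE = sum(M * g^2) / Nr,
    GLRLM_SRHGE = sum(M * g^2 / l^2) / Nr,
    GLRLM_GLNU = sum(rowSums(M)^2) / Nr,
    GLRLM_RLNU = sum(colSums(M)^2) / Nr,
    GLRLM_RP = Nr / n_pixels
  )
}
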