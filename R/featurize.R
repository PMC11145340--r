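# Assembly of the 16-dimensional handcrafted feature vector.

#' Fixed order of the 16 handcrafted nucleus features
#'
#' Nine geometric features followed by seven texture features; every
#' feature table in the package uses exactly this column order.
#' @export
nucmil_feature_names <- c(
  "Major", "Minor", "Area", "theta", "Ecc", "Ell", "Dia", "Per",
  "AreaHull",
  "Con", "Diss", "Hom", "Ent", "ASM", "Rou", "Dsip")

#' Compute the 16-dimensional handcrafted feature vector of one nucleus
#'
#' @param region a [nucleus_region()]
#' @param diagonal_weight passed to [boundary_counts()]
#' @return named numeric vector of length 16 in the order of
#'   [nucmil_feature_names]
#' @export
featurize_nucleus <- function(region, diagonal_weight = 2) {
  geo <- geometric_features(region, diagonal_weight)
  tex <- texture_features(region, geo)
  out <- c(Major = geo$Major, Minor = geo$Minor, Area = geo$Area,
           theta = geo$theta, Ecc = geo$Ecc, Ell = geo$Ell,
           Dia = geo$Dia, Per = geo$Per, AreaHull = geo$AreaHull,
           tex)
  out[nucmil_feature_names]
}

#' Feature table for every nucleus in a labeled tile
#'
#' @param gray_tile 8-bit gray image matrix
#' @param instance_mask integer instance mask (0 = background)
#' @param gray_levels gray bins for the texture features
#' @param tile_id optional identifier copied into the table
#' @param min_area instances smaller than this are skipped
#' @return data.frame with `tile_id`, `nucleus`, centroid `x`, `y` (tile
#'   coordinates) and the 16 feature columns
#' @export
featurize_mask <- function(gray_tile, instance_mask, gray_levels = 8L,
                           tile_id = NA_character_, min_area = 4L) {
  regions <- split_instances(gray_tile, instance_mask, gray_levels, min_area)
  if (!length(regions)) {
    empty <- as.data.frame(matrix(numeric(0), 0L, 16L,
                                  dimnames = list(NULL, nucmil_feature_names)))
    return(cbind(data.frame(tile_id = character(0), nucleus = integer(0),
                            x = numeric(0), y = numeric(0)), empty))
  }
  rows <- lapply(names(regions), function(k) {
    rg <- regions[[k]]
    mo <- compute_moments(rg)
    fv <- featurize_nucleus(rg)
    cbind(data.frame(tile_id = tile_id, nucleus = as.integer(k),
                     x = rg$offset[1L] + mo$centroid[["x"]],
                     y = rg$offset[2L] + mo$centroid[["y"]]),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Fit z-normalisation statistics for a feature table
#'
#' @param feats data.frame or matrix holding the 16 feature columns
#' @return list with per-feature `mean` and `sd` (zero sds replaced by 1)
#' @export
fit_feature_scaler <- function(feats) {
  m <- as.matrix(feats[, nucmil_feature_names, drop = FALSE])
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

#' Apply z-normalisation statistics to a feature matrix
#' @param feats matrix/data.frame with the 16 feature columns
#' @param scaler output of [fit_feature_scaler()]
#' @return numeric matrix of z-scores, columns in feature order
#' @export
scale_features <- function(feats, scaler) {
  m <- as.matrix(feats[, nucmil_feature_names, drop = FALSE])
  sweep(sweep(m, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}
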