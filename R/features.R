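#' Names of the 22 image features
#'
#' Canonical order used by [extract_all()] and the CSV interfaces.
#' @return character vector of length 22.
#' @export
feature_names <- function() {
  c("contrast", "skewness", "kurtosis", "horizontal_balance",
    "vertical_balance", "first_order_entropy", "edge_density",
    "symmetry_lr", "symmetry_ud", "symmetry_lrud", "self_similarity",
    "complexity_gs", "anisotropy", "ft_mean", "ft_std", "gbmr_mean",
    "gbmr_std", "n_colors", "hue_avg", "hue_std", "saturation",
    "brightness")
}

#' Color features from a generator color log
#'
#' The log lists every distinct particle color (hue rounded to one degree,
#' with the sequence's constant saturation/brightness). Hue statistics are
#' linear (not circular) mean/SD over the logged hues.
#'
#' @param log data frame with columns `hue_deg`, `saturation`,
#'   `brightness` (one row per distinct color).
#' @return named vector `c(n_colors, hue_avg, hue_std, saturation,
#'   brightness)`.
#' @export
color_features <- function(log) {
  if (is.null(log) || nrow(log) == 0) stop("empty color log")
  hs <- log$hue_deg
  c(n_colors = nrow(log),
    hue_avg = mean(hs),
    hue_std = if (length(hs) > 1) stats::sd(hs) else 0,
    saturation = log$saturation[1],
    brightness = log$brightness[1])
}

#' Extract all 22 image features
#'
#' Runs the full battery on one RGB image plus its sequence color log:
#' luminance statistics, balance, Gabor orientation features, PHOG
#' features, symmetry scores, both saliency maps, and the color features.
#' Deterministic on fixed input.
#'
#' @param img `h x w x 3` RGB array in \[0, 255\].
#' @param log color-log data frame for the image's sequence.
#' @return named numeric vector with the entries of [feature_names()].
#' @export
extract_all <- function(img, log) {
  g <- to_gray(img)
  mom <- luminance_moments(g)
  com <- balance_com(g)
  oh <- orientation_histogram(g)
  ph <- phog_features(g)
  sym <- symmetry_scores(img)
  ft <- saliency_stats(ft_saliency(img))
  gb <- saliency_stats(gbmr_saliency(img))
  col <- color_features(log)
  out <- c(contrast = rms_contrast(g),
           skewness = unname(mom["skewness"]),
           kurtosis = unname(mom["kurtosis"]),
           horizontal_balance = unname(com["horizontal"]),
           vertical_balance = unname(com["vertical"]),
           first_order_entropy = first_order_entropy(oh),
           edge_density = edge_density(g),
           symmetry_lr = unname(sym["lr"]),
           symmetry_ud = unname(sym["ud"]),
           symmetry_lrud = unname(sym["lrud"]),
           self_similarity = unname(ph["self_similarity"]),
           complexity_gs = unname(ph["complexity_gs"]),
           anisotropy = unname(ph["anisotropy"]),
           ft_mean = unname(ft["mean"]), ft_std = unname(ft["std"]),
           gbmr_mean = unname(gb["mean"]), gbmr_std = unname(gb["std"]),
           n_colors = unname(col["n_colors"]),
           hue_avg = unname(col["hue_avg"]),
           hue_std = unname(col["hue_std"]),
           saturation = unname(col["saturation"]),
           brightness = unname(col["brightness"]))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Feature table for one image sequence
#'
#' @param seq an `image_sequence` from [run_simulation()].
#' @return data frame with `sequence_id`, `time_s` and the 22 features,
#'   one row per sampled image.
#' @export
extract_sequence_features <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  rows <- lapply(seq_along(seq$images), function(k)
    extract_all(seq$images[[k]], seq$color_log))
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(sequence_id = seq$sequence_id,
                   time_s = seq$sample_times), out)
}

#' Feature table for a list of sequences
#'
#' @param sequences list of `image_sequence` objects.
#' @return row-bound feature table (one row per image).
#' @export
extract_study_features <- function(sequences) {
  do.call(rbind, lapply(sequences, extract_sequence_features))
}
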