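#' Wide spectra tables
#'
#' Multivariate operations work on wide tibbles: one row per spectrum, label
#' columns (e.g. `molecule`, `conc_bsa`, `conc_blg`) plus one numeric-named
#' column per grid position (the column name is the wavenumber in cm^-1).
#' `spectra_matrix()` assembles such a table; `spectra_grid()` and
#' `spectra_values()` pull the shared grid and the numeric matrix back out.
#'
#' @param values Numeric matrix, rows = spectra, columns = grid points.
#' @param grid Wavenumber grid, cm^-1 (length = ncol(values)).
#' @param labels Optional data frame of per-row labels.
#' @return A tibble with label columns followed by spectral columns.
#' @export
spectra_matrix <- function(values, grid, labels = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(grid)) {
    abort("`grid` length must match ncol(values).")
  }
  if (anyNA(values)) abort("Spectra tables may not contain missing values.")
  sp <- as_tibble(values, .name_repair = "minimal")
  names(sp) <- format_grid_names(grid)
  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    if (nrow(labels) != nrow(sp)) abort("`labels` must have one row per spectrum.")
    sp <- dplyr::bind_cols(labels, sp)
  }
  sp
}

format_grid_names <- function(grid) sprintf("%.10g", grid)

spectra_column_names <- function(data) {
  nm <- names(data)
  nm[grepl("^[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?$", nm)]
}

#' @rdname spectra_matrix
#' @param data A wide spectra tibble.
#' @export
spectra_grid <- function(data) {
  as.numeric(spectra_column_names(data))
}

#' @rdname spectra_matrix
#' @export
spectra_values <- function(data) {
  cols <- spectra_column_names(data)
  if (length(cols) == 0) abort("No spectral (numeric-named) columns found.")
  m <- as.matrix(data[, cols])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("Spectra tables may not contain missing values.")
  m
}

#' Principal component scores of a spectra table
#'
#' Mean-centred singular value decomposition. Scores are orthogonal,
#' explained variances non-increasing and sum to the total variance.
#'
#' @param data Wide spectra tibble (see [spectra_matrix()]).
#' @param n_components Number of components (<= min(rows - 1, columns)).
#' @return A list of class `pca_result`: `scores` (tibble, labels +
#'   `PC1..PCk`), `loadings` (matrix), `explained_variance`, `center`.
#' @export
pca_scores <- function(data, n_components = 2) {
  x <- spectra_values(data)
  if (nrow(x) < 2) abort("PCA needs at least 2 spectra.")
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_components > kmax) {
    abort(sprintf("`n_components` must be <= %d for this table.", kmax))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  lab <- data[, setdiff(names(data), spectra_column_names(data)), drop = FALSE]
  scores <- dplyr::bind_cols(
    as_tibble(lab),
    as_tibble(pc$x[, seq_len(k), drop = FALSE], .name_repair = "minimal"))
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = pc$sdev^2,
                 center = pc$center),
            class = "pca_result")
}

#' Linear-kernel SVM molecule classifier
#'
#' One-vs-rest linear support vector machines (cost parameter C, default
#' 1.0), trained on a seeded stratified split (default 80 percent train /
#' 20 percent test, split by sample so no spectrum appears in both halves);
#' reports held-out accuracy and the confusion table.
#'
#' @param data Wide spectra tibble with a `label_col` class column.
#' @param label_col Name of the class column.
#' @param split_fraction Training fraction in (0, 1).
#' @param cost SVM regularization parameter C.
#' @param seed Integer seed for the split.
#' @return A list of class `svm_classifier`: `models` (per-class binary
#'   SVMs), `classes`, `test_accuracy`, `confusion` (tibble), `split`
#'   (row indices).
#' @export
train_classifier <- function(data, label_col = "molecule",
                             split_fraction = 0.8, cost = 1, seed = 0) {
  if (!label_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", label_col))
  }
  y <- as.character(data[[label_col]])
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("Need at least 2 classes.")
  if (min(table(y)) < 2) abort("Need at least 2 samples per class.")
  x <- spectra_values(data)
  idx_train <- stratified_split(y, split_fraction, seed)
  idx_test <- setdiff(seq_along(y), idx_train)
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y[idx_train] == cl, cl, "rest"),
                 levels = c(cl, "rest"))
    e1071::svm(x[idx_train, , drop = FALSE], yy, kernel = "linear",
               cost = cost, scale = FALSE)
  })
  names(models) <- classes
  pred <- predict_ovr(models, classes, x[idx_test, , drop = FALSE])
  acc <- mean(pred == y[idx_test])
  confusion <- as_tibble(table(truth = y[idx_test], predicted = pred))
  structure(list(models = models, classes = classes,
                 test_accuracy = acc, confusion = confusion,
                 split = list(train = idx_train, test = idx_test)),
            class = "svm_classifier")
}

stratified_split <- function(y, split_fraction, seed) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("`split_fraction` must be in (0, 1).")
  }
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
    n_tr <- max(1, round(split_fraction * length(ii)))
    sample(ii, n_tr)
  }), use.names = FALSE)
  sort(idx)
}

predict_ovr <- function(models, classes, x) {
  dec <- vapply(classes, function(cl) {
    d <- attr(predict(models[[cl]], x, decision.values = TRUE),
              "decision.values")
    dv <- d[, 1]
    # orient so larger = more like `cl`
    if (grepl(paste0("^", cl, "/"), colnames(d)[1])) dv else -dv
  }, numeric(nrow(x)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  classes[apply(dec, 1, which.max)]
}

#' @rdname train_classifier
#' @param classifier An `svm_classifier`.
#' @param newdata Wide spectra tibble.
#' @export
predict_classifier <- function(classifier, newdata) {
  predict_ovr(classifier$models, classifier$classes, spectra_values(newdata))
}

#' Non-negative spectral unmixing
#'
#' Decomposes a mixture spectrum as a non-negative combination of reference
#' spectra by non-negative least squares, and reports the reconstruction and
#' its mean squared error. Weights are scale-equivariant: scaling the
#' mixture by s scales the weights by s.
#'
#' @param mixture A [seira_spectrum()].
#' @param references Wide spectra tibble of references (rows), sharing the
#'   mixture grid; an optional label column names the weights.
#' @param label_col Optional reference-name column.
#' @param window Optional `c(lower, upper)` wavenumber range (cm^-1): the
#'   least-squares fit is restricted to this band (e.g. the protein
#'   fingerprint region), which suppresses the leverage of broad out-of-band
#'   baseline error; the reconstruction and MSE are still reported on the
#'   full grid.
#' @return A list of class `unmix_result`: `weights` (named, >= 0),
#'   `reconstructed` ([seira_spectrum()]), `mse`.
#' @export
nnls_unmix <- function(mixture, references, label_col = NULL, window = NULL) {
  mixture <- as_spectrum_like(mixture)
  refs <- spectra_values(references)
  grid <- spectra_grid(references)
  if (length(grid) != nrow(mixture) ||
      max(abs(grid - mixture$wavenumber)) > 1e-6 * max(abs(grid))) {
    abort("References must share the mixture grid.")
  }
  a <- t(refs)
  sel <- if (is.null(window)) rep(TRUE, length(grid)) else {
    grid >= window[1] & grid <= window[2]
  }
  if (sum(sel) <= nrow(refs)) abort("`window` leaves too few grid points.")
  sol <- pracma::lsqnonneg(a[sel, , drop = FALSE], mixture$value[sel])
  w <- sol$x
  nms <- if (!is.null(label_col) && label_col %in% names(references)) {
    as.character(references[[label_col]])
  } else {
    lab <- setdiff(names(references), spectra_column_names(references))
    if (length(lab) > 0) as.character(references[[lab[1]]])
    else paste0("ref", seq_len(nrow(refs)))
  }
  names(w) <- nms
  recon <- as.numeric(a %*% w)
  structure(list(weights = w,
                 reconstructed = seira_spectrum(grid, recon,
                                                kind = spectrum_kind(mixture)),
                 mse = mean((mixture$value - recon)^2)),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result> weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  reconstruction MSE = %.4g\n", x$mse))
  invisible(x)
}

#' Titration-set unmixing pipeline
#'
#' End-to-end analysis of a simulated (or measured) two-protein titration
#' table: every absorbance row is baseline-extracted, rows are averaged per
#' concentration pair (the titration set is the experimental unit — each
#' mixture is measured as a set of replicate spectra), the pure endpoint
#' sets serve as references, and each set-averaged difference spectrum is
#' unmixed by non-negative least squares restricted to the protein
#' fingerprint window.
#'
#' @param data Wide spectra tibble with `conc_bsa`, `conc_blg` labels
#'   (percent) and absorbance rows, e.g. from
#'   [simulate_titration_dataset()].
#' @param config An [asls_config()] for the extraction.
#' @param window Fit window (cm^-1) for the unmixing, default the Amide
#'   I/II region.
#' @return Tibble with one row per concentration pair: `conc_bsa`,
#'   `conc_blg`, recovered `weight_bsa`, `weight_blg` (sum-normalized) and
#'   reconstruction `mse`.
#' @export
unmix_titration <- function(data, config = asls_config(),
                            window = c(1450, 1750)) {
  if (!all(c("conc_bsa", "conc_blg") %in% names(data))) {
    abort("`data` needs `conc_bsa` and `conc_blg` labels.")
  }
  grid <- spectra_grid(data)
  vals <- spectra_values(data)
  ex <- t(vapply(seq_len(nrow(vals)), function(i) {
    extract_difference(
      seira_spectrum(grid, vals[i, ], kind = "absorbance",
                     meta = list(noise_tol = 1)),
      config)$value
  }, numeric(length(grid))))
  wfrac <- data$conc_bsa / (data$conc_bsa + data$conc_blg)
  if (!any(wfrac == 1) || !any(wfrac == 0)) {
    abort("Titration table must contain pure BSA and pure BLG sets.")
  }
  set_mean <- function(w) colMeans(ex[wfrac == w, , drop = FALSE])
  refs <- spectra_matrix(rbind(set_mean(1), set_mean(0)), grid,
                         labels = tibble(ref = c("bsa", "blg")))
  purrr::map_dfr(sort(unique(wfrac), decreasing = TRUE), function(w) {
    ms <- seira_spectrum(grid, set_mean(w), kind = "difference")
    um <- nnls_unmix(ms, refs, window = window)
    tot <- sum(um$weights)
    tibble(conc_bsa = 100 * w, conc_blg = 100 * (1 - w),
           weight_bsa = um$weights[["bsa"]] / tot,
           weight_blg = um$weights[["blg"]] / tot,
           mse = um$mse)
  })
}

#' Amide-I secondary-structure summary
#'
#' Segments the second-derivative spectrum of the Amide-I region
#' (1600-1700 cm^-1) into contiguous negative lobes, assigns each lobe to
#' the conformational band containing its minimum (alpha-helix near
#' 1657 cm^-1, beta-sheet in the low- and high-frequency wings, otherwise
#' "other"), integrates the lobe magnitudes and normalizes to fractions.
#' The default band windows are literature-informed and overridable.
#'
#' @param second_derivative A derivative2-kind [seira_spectrum()] covering
#'   1600-1700 cm^-1.
#' @param band_table Data frame with `structure`, `lower`, `upper` (cm^-1).
#'   Uncovered remainder of 1600-1700 is assigned to `"other"`.
#' @return A list of class `structure_summary` with `band_fractions`
#'   (tibble: `structure`, `fraction`) summing to 1.
#' @export
secondary_structure <- function(second_derivative,
                                band_table = amide1_band_table()) {
  sp <- as_spectrum_like(second_derivative)
  if (spectrum_kind(sp) != "derivative2") {
    abort("`secondary_structure()` expects a second-derivative spectrum.")
  }
  if (min(sp$wavenumber) > 1600 || max(sp$wavenumber) < 1700) {
    abort("Grid must cover the Amide-I region (1600-1700 cm^-1).")
  }
  in_amide <- sp$wavenumber >= 1600 & sp$wavenumber <= 1700
  wn <- sp$wavenumber[in_amide]
  neg <- pmax(-sp$value[in_amide], 0)
  if (all(neg == 0)) {
    abort("Second derivative has no negative lobes in the Amide-I region.")
  }
  runs <- rle(neg > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lobes <- purrr::map_dfr(which(runs$values), function(k) {
    ii <- starts[k]:ends[k]
    if (length(ii) < 2) return(tibble())
    # split merged lobes at interior valleys so overlapping sub-bands are
    # attributed separately
    v <- neg[ii]
    interior <- which(diff(sign(diff(v))) > 0) + 1L
    interior <- interior[v[interior] < 0.9 * max(v)]
    cuts <- c(1L, interior, length(ii))
    purrr::map_dfr(seq_len(length(cuts) - 1L), function(s) {
      jj <- ii[cuts[s]:cuts[s + 1L]]
      if (length(jj) < 2) return(tibble())
      tibble(minimum = wn[jj][which.max(neg[jj])],
             area = pracma::trapz(wn[jj], neg[jj]))
    })
  })
  lobes$structure <- purrr::map_chr(lobes$minimum, function(m) {
    hit <- band_table$structure[m >= band_table$lower & m < band_table$upper]
    if (length(hit) == 0) "other" else hit[1]
  })
  frac <- lobes %>%
    dplyr::group_by(.data$structure) %>%
    dplyr::summarise(fraction = sum(.data$area), .groups = "drop")
  missing <- setdiff(c(unique(band_table$structure), "other"), frac$structure)
  if (length(missing) > 0) {
    frac <- dplyr::bind_rows(frac, tibble(structure = missing, fraction = 0))
  }
  frac$fraction <- frac$fraction / sum(frac$fraction)
  structure(list(band_fractions = dplyr::arrange(frac, dplyr::desc(.data$fraction))),
            class = "structure_summary")
}

#' @rdname secondary_structure
#' @export
amide1_band_table <- function() {
  tibble(structure = c("alpha_helix", "beta_sheet", "beta_sheet"),
         lower = c(1648, 1620, 1670),
         upper = c(1660, 1640, 1690))
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("<structure_summary> Amide-I band fractions:\n")
  print(x$band_fractions)
  invisible(x)
}
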