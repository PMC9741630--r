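# The two physics-constrained hybrid models and the canopy-water-storage
# (CWS) latent-variable network. Each hybrid model maps standardized
# environmental predictors (plus one-hot PFT) to the log surface resistance
# ln Rs; the loss compares observed LE with the quadratic Penman-Monteith
# forward transform of exp(ln Rs), so every prediction conserves the
# surface energy balance. HM_dry is trained on dry hours only; HM_wet on
# wet (in-event) hours with CWS as an extra predictor. Their difference on
# identical wet-hour forcing is the interception-evaporation estimate.

DRY_PREDICTORS <- c("Ta", "VPD", "Rn", "WS", "LAI")
WET_PREDICTORS <- c(DRY_PREDICTORS, "CWS")

#' Training configuration for the hybrid and CWS networks
#'
#' @param hidden hidden-layer sizes
#' @param epochs,batch,lr,patience optimizer controls
#' @param warm_epochs epochs of warm-start regression on inverted ln Rs
#'   targets before the physics-loss fine-tune
#' @param min_samples minimum training-set size for a hybrid model
#' @param seed RNG seed
#' @export
hybrid_config <- function(hidden = c(64, 64), epochs = 250L, batch = 512L,
                          lr = 2e-3, patience = 30L, warm_epochs = 100L,
                          min_samples = 1000L, seed = 7L) {
  list(hidden = hidden, epochs = as.integer(epochs), batch = as.integer(batch),
       lr = lr, patience = as.integer(patience),
       warm_epochs = as.integer(warm_epochs),
       min_samples = as.integer(min_samples), seed = as.integer(seed))
}

#' Assemble training/prediction samples from a labelled site series
#'
#' Attaches available energy A = Rn - G and the aerodynamic resistance from
#' the neutral wind profile, plus the site PFT, to every hour.
#'
#' @param series site_series (QC columns optional)
#' @param labels factor from [label_hours()]
#' @return data.frame of model samples with hour_idx
#' @export
build_samples <- function(series, labels) {
  meta <- attr(series, "meta")
  ra <- aerodynamic_resistance(series$WS, meta$tower_height,
                               meta$canopy_height)
  data.frame(hour_idx = seq_len(nrow(series)),
             Ta = series$Ta, VPD = series$VPD, Rn = series$Rn, G = series$G,
             WS = series$WS, LAI = series$LAI, P = series$P,
             LE_obs = series$LE, hod = series$hod,
             A = series$Rn - series$G, ra = ra,
             pft = if (!is.null(series$pft)) series$pft else meta$pft,
             label = labels, stringsAsFactors = FALSE)
}

.onehot_pft <- function(pft) {
  m <- sapply(PFT8, function(p) as.numeric(pft == p))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, PFT8))
  colnames(m) <- paste0("pft_", PFT8)
  m
}

.feature_matrix <- function(df, numeric_vars, stats = NULL) {
  X <- as.matrix(df[numeric_vars])
  if (is.null(stats)) {
    stats <- list(mean = colMeans(X), sd = apply(X, 2, stats::sd))
    stats$sd[stats$sd == 0 | !is.finite(stats$sd)] <- 1
  }
  Xs <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
  list(X = cbind(Xs, .onehot_pft(df$pft)), stats = stats)
}

#' Train a physics-constrained hybrid model
#'
#' The network regresses ln Rs on standardized predictors; training
#' minimizes the mean squared error between observed LE and the quadratic
#' Penman-Monteith forward transform of the predicted resistance. The net
#' is warm-started on ln Rs targets obtained by closed-form inversion of
#' the observed LE. Hours where that inversion is undefined are excluded
#' from training. A 10% held-out split provides the recorded r2/RMSE.
#'
#' @param samples data.frame from [build_samples()]
#' @param flavor "dry" or "wet"
#' @param cws canopy-water-storage predictor (W m-2), aligned with samples;
#'   required when flavor = "wet"
#' @param config [hybrid_config()]
#' @param max_samples cap on training-set size (subsampled, seeded)
#' @return hybrid_model object
#' @export
train_hybrid <- function(samples, flavor = c("dry", "wet"), cws = NULL,
                         config = hybrid_config(), max_samples = 30000L) {
  flavor <- match.arg(flavor)
  if (flavor == "wet") {
    if (is.null(cws) || length(cws) != nrow(samples))
      stop("wet flavor needs a CWS predictor aligned with samples")
    samples$CWS <- cws
  } else if (!is.null(cws)) stop("dry flavor takes no CWS predictor")
  want <- if (flavor == "dry") "dry" else "wet"
  keep <- samples$label == want & stats::complete.cases(
    samples[c(if (flavor == "dry") DRY_PREDICTORS else WET_PREDICTORS,
              "LE_obs", "A", "ra")])
  df <- samples[keep, , drop = FALSE]
  if (nrow(df) == 0L || !any(samples$label == want, na.rm = TRUE))
    stop("no samples of flavor '", want, "'")
  st_all <- pm_state(df$Ta, df$VPD, df$A, df$ra)
  inv <- pm_invert(df$LE_obs, st_all)
  df <- df[inv$defined, , drop = FALSE]
  lnrs <- log(pmax(inv$Rs[inv$defined], 1))
  if (nrow(df) < config$min_samples)
    stop("too few trainable samples (", nrow(df), " < ",
         config$min_samples, ")")
  set.seed(config$seed)
  if (nrow(df) > max_samples) {
    sub <- sample.int(nrow(df), max_samples)
    df <- df[sub, , drop = FALSE]; lnrs <- lnrs[sub]
  }
  # held-out rows for the recorded skill metrics
  n <- nrow(df)
  hold <- sample.int(n, max(1L, floor(0.1 * n)))
  trn <- setdiff(seq_len(n), hold)

  preds <- if (flavor == "dry") DRY_PREDICTORS else WET_PREDICTORS
  fm <- .feature_matrix(df[trn, , drop = FALSE], preds)
  st <- pm_state(df$Ta, df$VPD, df$A, df$ra)
  warm <- mlp_train(fm$X, lnrs[trn], loss = "mse", hidden = config$hidden,
                    epochs = config$warm_epochs, batch = config$batch,
                    lr = config$lr, patience = config$patience,
                    seed = config$seed, out_bias = mean(lnrs[trn]))
  fit <- mlp_train(fm$X, df$LE_obs[trn], loss = "physics",
                   state = st[trn, , drop = FALSE], hidden = config$hidden,
                   epochs = config$epochs, batch = config$batch,
                   lr = config$lr / 2, patience = config$patience,
                   seed = config$seed + 1L, init = warm$net)
  model <- structure(
    list(flavor = flavor, predictors = preds, stats = fm$stats,
         net = fit$net, seed = config$seed, config = config,
         history = list(warm = warm$history, physics = fit$history)),
    class = "hybrid_model")
  held <- df[hold, , drop = FALSE]
  le_hat <- predict_le(model, held)
  r <- held$LE_obs - le_hat
  model$metrics <- list(
    n_train = length(trn), n_holdout = length(hold),
    rmse = sqrt(mean(r^2)),
    r2 = 1 - sum(r^2) / sum((held$LE_obs - mean(held$LE_obs))^2))
  le_trn <- predict_le(model, df[trn, , drop = FALSE])
  model$metrics$rmse_train <- sqrt(mean((df$LE_obs[trn] - le_trn)^2))
  model
}

#' Predict LE with a hybrid model
#'
#' LE = pm_forward(exp(net(features))): non-negative and energy-conserving
#' by construction. Features more than 10 SD outside the training
#' distribution trigger an extrapolation warning but are still predicted.
#'
#' @param model hybrid_model
#' @param samples data.frame carrying the model's predictors plus A and ra
#' @return LE in W m-2
#' @export
predict_le <- function(model, samples) {
  miss <- setdiff(model$predictors, names(samples))
  if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
  fm <- .feature_matrix(samples, model$predictors, model$stats)
  k <- length(model$predictors)
  if (any(abs(fm$X[, seq_len(k), drop = FALSE]) > 10, na.rm = TRUE))
    warning("some features lie > 10 SD outside the training distribution")
  z <- pmin(pmax(mlp_forward(model$net, fm$X), -5), 14)
  st <- pm_state(samples$Ta, samples$VPD, samples$A, samples$ra)
  pmax(pm_forward(exp(z), st), 0)
}

#' Canopy-water-storage proxy from the dry-model residual
#'
#' CWS_h = LE_obs,h - LE_dry_hat,h on wet hours; negative values are
#' marked for removal from the CWS training set (measurement noise).
#'
#' @param LE_obs observed LE on wet hours (W m-2)
#' @param LE_dry_hat HM_dry counterfactual on the same hours
#' @param label optional label vector; anything not "wet" is an error
#' @return data.frame with cws and keep (non-negative) columns
#' @export
derive_cws_proxy <- function(LE_obs, LE_dry_hat, label = NULL) {
  if (!is.null(label) && any(label != "wet"))
    stop("CWS proxy is defined on wet hours only")
  if (length(LE_obs) != length(LE_dry_hat)) stop("series must be aligned")
  cws <- LE_obs - LE_dry_hat
  data.frame(cws = cws, keep = cws >= 0)
}

.cws_numeric <- function(df) {
  d <- data.frame(LAI = df$LAI,
                  cum_P_event = df$cum_P_event,
                  mean_P_event = df$mean_P_event,
                  max_P_event = df$max_P_event,
                  P_now = df$P_now,
                  cum_P_last_pulse = df$cum_P_last_pulse,
                  max_P_last_pulse = df$max_P_last_pulse,
                  dry_hours_since_pulse = df$dry_hours_since_pulse,
                  pulse_end_sin = sin(2 * pi * df$last_pulse_end_hod / 24),
                  pulse_end_cos = cos(2 * pi * df$last_pulse_end_hod / 24))
  d
}

#' Train the CWS latent-variable network
#'
#' Regresses the CWS proxy (W m-2) on vegetation state (LAI, PFT) and the
#' eight rainfall descriptors; plain MSE loss. Only wet hours with a
#' non-negative proxy are used.
#'
#' @param descriptors data.frame with LAI, pft and the eight descriptor
#'   columns (see [event_descriptor_table()])
#' @param proxy CWS proxy (W m-2) aligned with descriptors
#' @param config [hybrid_config()]; a lighter net is typically enough
#' @param min_samples minimum usable rows
#' @return cws_model object
#' @export
train_cws_net <- function(descriptors, proxy, config = hybrid_config(),
                          min_samples = 500L) {
  keep <- is.finite(proxy) & proxy >= 0 &
    stats::complete.cases(.cws_numeric(descriptors))
  df <- descriptors[keep, , drop = FALSE]
  y <- proxy[keep]
  if (nrow(df) < min_samples)
    stop("too few wet training hours (", nrow(df), " < ", min_samples, ")")
  if (stats::sd(y) < 1e-9) {
    warning("degenerate constant CWS proxy; returning a constant model")
    return(structure(list(constant = mean(y)), class = "cws_model"))
  }
  num <- .cws_numeric(df)
  X <- as.matrix(num)
  stats_ <- list(mean = colMeans(X), sd = apply(X, 2, stats::sd))
  stats_$sd[stats_$sd == 0 | !is.finite(stats_$sd)] <- 1
  Xs <- sweep(sweep(X, 2, stats_$mean), 2, stats_$sd, "/")
  Xs <- cbind(Xs, .onehot_pft(df$pft))
  fit <- mlp_train(Xs, y, loss = "mse", hidden = config$hidden,
                   epochs = config$epochs, batch = config$batch,
                   lr = config$lr, patience = config$patience,
                   seed = config$seed + 2L, out_bias = mean(y))
  structure(list(net = fit$net, stats = stats_, val_loss = fit$val_loss,
                 seed = config$seed), class = "cws_model")
}

#' Predict CWS (W m-2) for wet hours
#'
#' @param model cws_model
#' @param descriptors data.frame with LAI, pft and the eight descriptors
#' @return CWS in W m-2
#' @export
predict_cws <- function(model, descriptors) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(descriptors)))
  X <- as.matrix(.cws_numeric(descriptors))
  Xs <- sweep(sweep(X, 2, model$stats$mean), 2, model$stats$sd, "/")
  Xs <- cbind(Xs, .onehot_pft(descriptors$pft))
  mlp_forward(model$net, Xs)
}
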