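AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Build a position-weight-matrix domain profile
#'
#' A domain profile is a per-column amino-acid probability model scored
#' against a background; windows of an ORF are scored by summed log2-odds.
#' Profiles fill the role of the curated family models of domain databases
#' in a pluggable scanner contract: any scanner returning
#' `(orf_id, domain_id, score, e_value)` can replace [scan_domains()].
#'
#' @param domain_id accession-style identifier (e.g. `"PF00001"`).
#' @param probs 20 x W matrix of column probabilities (rows in the fixed
#'   amino-acid order `AA20`, columns summing to 1), or a character
#'   consensus string from which a peaked profile is built.
#' @param background length-20 background frequencies (default uniform).
#' @param peak when `probs` is a consensus string, probability mass placed
#'   on the consensus residue per column (default 0.9).
#' @return A `domain_profile` (uncalibrated: no e-values until
#'   [calibrate_profile()] is applied).
#' @export
domain_profile <- function(domain_id, probs, background = rep(1/20, 20),
                           peak = 0.9) {
  stopifnot(length(background) == 20, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  if (is.character(probs) && length(probs) == 1L) {
    cons <- strsplit(probs, "")[[1]]
    stopifnot(all(cons %in% AA20))
    W <- length(cons)
    m <- matrix((1 - peak) / 19, nrow = 20, ncol = W, dimnames = list(AA20, NULL))
    for (j in seq_len(W)) m[cons[j], j] <- peak
    probs <- m
  }
  stopifnot(is.matrix(probs), nrow(probs) == 20,
            all(abs(colSums(probs) - 1) < 1e-9), all(probs > 0))
  rownames(probs) <- AA20
  pwm <- log2(probs / background)
  consensus <- paste(AA20[apply(pwm, 2, which.max)], collapse = "")
  structure(list(domain_id = domain_id, probs = probs, pwm = pwm,
                 background = stats::setNames(background, AA20),
                 width = ncol(probs), consensus = consensus,
                 gumbel_mu = NA_real_, gumbel_beta = NA_real_),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %s  width %d  %s\n", x$domain_id, x$width,
              if (is.na(x$gumbel_mu)) "uncalibrated"
              else sprintf("Gumbel(mu=%.2f, beta=%.2f)", x$gumbel_mu, x$gumbel_beta)))
  invisible(x)
}

# Gumbel maximum-likelihood fit (location mu, scale beta) via profile
# likelihood in beta; standard fixed-point form solved by uniroot.
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  m <- mean(x)
  y <- x - m  # center for numerical stability of exp(-x/beta)
  f <- function(beta) {
    w <- exp(-y / beta)
    beta - mean(y) + sum(y * w) / sum(w)
  }
  s <- stats::sd(y)
  beta <- tryCatch(stats::uniroot(f, c(s / 10, s * 10))$root,
                   error = function(e) s * sqrt(6) / pi)  # moment fallback
  mu <- m - beta * log(mean(exp(-y / beta)))
  list(mu = mu, beta = beta)
}

score_windows <- function(pwm, aa_idx) {
  W <- ncol(pwm)
  L <- length(aa_idx)
  nwin <- L - W + 1L
  if (nwin < 1L) return(numeric(0))
  s <- numeric(nwin)
  for (j in seq_len(W)) {
    col <- pwm[, j]
    v <- col[aa_idx[j:(j + nwin - 1L)]]
    v[is.na(v)] <- -10  # X or other non-standard residue: never matches
    s <- s + v
  }
  s
}

aa_to_idx <- function(aa) match(strsplit(aa, "")[[1]], AA20)

#' Calibrate a profile's e-value parameters
#'
#' Fits a Gumbel location/scale (`mu`, `beta`) by maximum likelihood to the
#' scores of `n` random width-W sequences drawn from the profile's background
#' frequencies. E-values are then computed as
#' `n_windows * exp(-(score - mu)/beta)`, the extreme-value tail for a scan
#' of `n_windows` windows.
#'
#' @param profile a `domain_profile`.
#' @param n number of calibration sequences (default 2000).
#' @param seed integer seed.
#' @return The profile with `gumbel_mu`/`gumbel_beta` set.
#' @export
calibrate_profile <- function(profile, n = 2000L, seed = 1L) {
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(20, profile$width, replace = TRUE, prob = profile$background)
      sum(profile$pwm[cbind(idx, seq_len(profile$width))])
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  profile$gumbel_mu <- fit$mu
  profile$gumbel_beta <- fit$beta
  profile
}

#' E-value of a window score under a calibrated profile
#' @param score best window score (bits).
#' @param n_windows number of windows scanned.
#' @param profile a calibrated `domain_profile`.
#' @export
profile_evalue <- function(score, n_windows, profile) {
  if (is.na(profile$gumbel_mu)) stop("profile ", profile$domain_id, " is not calibrated")
  n_windows * exp(-(score - profile$gumbel_mu) / profile$gumbel_beta)
}

#' Scan ORFs for domain hits
#'
#' Slides each calibrated profile over each ORF, keeps the best window score
#' per (ORF, profile), converts it to an e-value, and reports hits below
#' `evalue_max` (default 1e-4, the conventional counting threshold).
#' Profiles wider than an ORF are skipped for that ORF.
#'
#' @param orfs ORF data.frame from [extract_orfs()] (needs `orf_id`,
#'   `aa_seq`; `read_id`/`frame` carried through when present).
#' @param profiles list of calibrated `domain_profile`s.
#' @param evalue_max report hits with `e_value < evalue_max`.
#' @return data.frame: `orf_id`, `read_id`, `frame`, `domain_id`, `score`
#'   (bits), `e_value`, sorted by `orf_id` then `e_value`.
#' @export
scan_domains <- function(orfs, profiles, evalue_max = 1e-4) {
  if (inherits(profiles, "domain_profile")) profiles <- list(profiles)
  empty <- data.frame(orf_id = character(0), read_id = character(0),
                      frame = character(0), domain_id = character(0),
                      score = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(orfs) == 0L || length(profiles) == 0L || evalue_max <= 0) return(empty)
  rows <- list()
  idx_list <- lapply(orfs$aa_seq, aa_to_idx)
  for (p in profiles) {
    if (is.na(p$gumbel_mu)) stop("profile ", p$domain_id, " is not calibrated")
    for (i in seq_len(nrow(orfs))) {
      s <- score_windows(p$pwm, idx_list[[i]])
      if (length(s) == 0L) next
      best <- max(s)
      ev <- profile_evalue(best, length(s), p)
      if (ev < evalue_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          orf_id = orfs$orf_id[i],
          read_id = if ("read_id" %in% names(orfs)) orfs$read_id[i] else NA_character_,
          frame = if ("frame" %in% names(orfs)) orfs$frame[i] else NA_character_,
          domain_id = p$domain_id, score = best, e_value = ev,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$orf_id, out$e_value, out$domain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample relative abundance of domain hits
#'
#' The percentage each domain contributes to a sample's total counted hits,
#' with cross-sample mean and standard deviation — the "% relative
#' abundance" layout of a functional-category comparison.
#'
#' @param hits data.frame with `domain_id` and `sample` columns (counted
#'   hits, i.e. already thresholded).
#' @param samples optional character vector fixing the sample set (samples
#'   with zero hits yield zero rows and a warning).
#' @return List: `table` (samples x domains percentage matrix),
#'   `summary` (data.frame `domain_id`, `mean`, `sd`).
#' @export
domain_abundance <- function(hits, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(hits$sample))
  domains <- sort(unique(hits$domain_id))
  mat <- matrix(0, nrow = length(samples), ncol = length(domains),
                dimnames = list(samples, domains))
  for (s in samples) {
    h <- hits[hits$sample == s, , drop = FALSE]
    if (nrow(h) == 0L) {
      warning("sample ", s, " has zero counted hits")
      next
    }
    tab <- table(h$domain_id)
    mat[s, names(tab)] <- 100 * as.numeric(tab) / nrow(h)
  }
  list(table = mat,
       summary = data.frame(domain_id = domains,
                            mean = colMeans(mat),
                            sd = apply(mat, 2, stats::sd),
                            stringsAsFactors = FALSE, row.names = NULL))
}

#' Write / read a domain profile as JSON text
#' @param profile a `domain_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  obj <- list(domain_id = profile$domain_id,
              probs = unclass(profile$probs),
              background = as.numeric(profile$background),
              gumbel_mu = profile$gumbel_mu,
              gumbel_beta = profile$gumbel_beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- domain_profile(obj$domain_id, matrix(obj$probs, nrow = 20),
                      background = obj$background)
  p$gumbel_mu <- obj$gumbel_mu
  p$gumbel_beta <- obj$gumbel_beta
  p
}
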