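## truncated-normal draw by resampling violators (bounds are far tails for
## every packaged row, so this is cheap)
.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:200) {
    bad <- which(x <= lower | x >= upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop("truncated sampling failed to respect bounds (mean ", mean,
       ", sd ", sd, ")")
}

## Positive draw with *moment-matched* truncation: a plain >0-truncated
## Normal(mean, sd) overshoots the target mean whenever the coefficient of
## variation is large (some published rows reach CV ~ 0.7), so the
## underlying normal parameters (mu, sigma) are solved such that the
## truncated distribution itself has the requested mean and SD.
## Closed-form moments of the left-truncated normal: with a = mu/sigma and
## hazard h = phi(a)/Phi(a), E = mu + sigma h, Var = sigma^2 (1 - a h - h^2).
.rpos_norm <- function(n, mean, sd) {
  if (mean <= 0) stop("positive features need a positive mean")
  t <- mean / sd
  if (t > 6) return(.rnorm_trunc(n, mean, sd, lower = 0))
  if (t <= 1.01)
    stop("SE too large relative to the mean for a positive distribution ",
         "(mean/SD = ", signif(t, 3), ")")
  ratio <- function(a) {
    h <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    (a + h) / sqrt(max(1 - a * h - h^2, 1e-12))
  }
  a <- stats::uniroot(function(a) ratio(a) - t, c(-8, 8), tol = 1e-12)$root
  h <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  sigma <- sd / sqrt(max(1 - a * h - h^2, 1e-12))
  .rnorm_trunc(n, a * sigma, sigma, lower = 0)
}

## map inlet-velocity features to template inlet node ids
.VEL_NODE <- c(vel_CCA_L = "in_ccaL", vel_CCA_R = "in_ccaR",
               vel_VA_L = "in_vaL", vel_VA_R = "in_vaR")

## Draw inlet velocities for n animals (columns vel_CCA_L, vel_CCA_R,
## vel_VA_L, vel_VA_R). In the 2-month diabetic arm (asymmetry on) the
## right CCA is coupled within-animal to the left: right = left * ratio
## with ratio ~ N(mR/mL, s), s chosen so the marginal SD of the right side
## still matches its table row.
.draw_velocity_block <- function(params, group, mode, n, asymmetry) {
  v <- matrix(0, n, length(.VEL_NODE),
              dimnames = list(NULL, names(.VEL_NODE)))
  for (f in names(.VEL_NODE)) {
    pr <- .param_row(params, f, group, mode)
    v[, f] <- .rpos_norm(n, pr$mean, pr$sd)
  }
  if (asymmetry && group == "2d") {
    prL <- .param_row(params, "vel_CCA_L", group, mode)
    prR <- .param_row(params, "vel_CCA_R", group, mode)
    rm_ <- prR$mean / prL$mean
    rs2 <- max(prR$sd^2 - rm_^2 * prL$sd^2, 0) / prL$mean^2
    ratio <- .rnorm_trunc(n, rm_, sqrt(rs2), lower = 0, upper = 1)
    v[, "vel_CCA_R"] <- v[, "vel_CCA_L"] * ratio
  }
  v
}

#' Sample one virtual animal
#'
#' Draws the 22 section areas and 7 bifurcation angles of the template
#' feature-wise from the group's Normal(mean, SE*sqrt(n)) distributions
#' (positive features use a moment-matched positive truncation so the
#' sampled mean and SD equal the table values exactly; angles are truncated
#' to (0, 180)), imposes them on the circle-of-Willis template, and draws
#' the four inlet velocities. Deterministic under a fixed seed.
#'
#' @param params group-parameter table ([default_group_params()]).
#' @param group experimental arm.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param asymmetry couple the right CCA velocity to the left within each
#'   2-month-diabetic animal (the arm's left/right flow asymmetry).
#' @param template network template to perturb.
#' @return object of class `virtual_animal`: `id`, `group`, `network`,
#'   `inlet_velocities` (cm/s, named by inlet node id).
#' @export
sample_animal <- function(params, group, seed = NULL, asymmetry = TRUE,
                          template = cow_template()) {
  if (!group %in% .GROUPS) stop("unknown group '", group, "'")
  .with_seed(seed, {
    areas <- numeric(22)
    for (i in 1:22) {
      pr <- .param_row(params, paste0("area_S", i), group, "any")
      areas[i] <- .rpos_norm(1, pr$mean, pr$sd)
    }
    angles <- numeric(7)
    for (i in 1:7) {
      pr <- .param_row(params, paste0("angle_", i), group, "any")
      angles[i] <- .rnorm_trunc(1, pr$mean, pr$sd, lower = 0, upper = 180)
    }
    net <- .apply_geometry(template, areas = setNames(areas, 1:22),
                           angles = setNames(angles, 1:7))
    vel <- .draw_velocity_block(params, group, "any", 1, asymmetry)[1, ]
    structure(list(id = NA_character_, group = group, network = net,
                   inlet_velocities = setNames(unname(vel),
                                               .VEL_NODE[names(vel)])),
              class = "virtual_animal")
  })
}

#' Cohort configuration
#'
#' @param counts named integer vector of per-arm animal counts; defaults to
#'   the four-arm design 1c=7, 1d=5, 2c=10, 2d=9.
#' @param seed master seed; per-animal seeds are drawn once from the
#'   master-seeded stream, so each animal is reproducible regardless of
#'   generation order.
#' @param asymmetry enable the 2d left/right velocity coupling.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(counts = .GROUP_N, seed = 1, asymmetry = TRUE) {
  counts <- counts[counts > 0]
  if (!length(counts) || !all(names(counts) %in% .GROUPS))
    stop("counts must be named by groups among ", paste(.GROUPS, collapse = ", "))
  structure(list(counts = counts, seed = seed, asymmetry = asymmetry),
            class = "cohort_config")
}

#' Sample a cohort of virtual animals
#'
#' @param cfg a [cohort_config()].
#' @param params group-parameter table.
#' @return list of `virtual_animal` objects with ids like `"2c_03"`.
#' @export
sample_cohort <- function(cfg = cohort_config(),
                          params = default_group_params()) {
  n_total <- sum(cfg$counts)
  seeds <- .with_seed(cfg$seed,
                      sample.int(.Machine$integer.max, n_total))
  out <- vector("list", n_total)
  k <- 0L
  for (g in names(cfg$counts)) {
    for (i in seq_len(cfg$counts[[g]])) {
      k <- k + 1L
      a <- sample_animal(params, g, seed = seeds[k],
                         asymmetry = cfg$asymmetry)
      a$id <- sprintf("%s_%02d", g, i)
      a$seed <- seeds[k]
      out[[k]] <- a
    }
  }
  out
}

#' Draw a feature matrix directly from the group distributions
#'
#' Bypasses the solver: every registry feature is drawn feature-wise from
#' its group distribution (the distributional-fidelity path used to test the
#' statistics stage at exactly the published group statistics). Optionally
#' appends the four inlet-velocity columns, with the 2d within-animal
#' left/right coupling.
#'
#' @param cfg a [cohort_config()].
#' @param params group-parameter table.
#' @param mode `"steady"` or `"transient"` (selects the mode-specific rows).
#' @param include_velocities append `vel_CCA_L/R`, `vel_VA_L/R` columns.
#' @return data.frame with columns `animal`, `group`, then one column per
#'   feature; attribute `mode`.
#' @export
direct_feature_matrix <- function(cfg = cohort_config(),
                                  params = default_group_params(),
                                  mode = c("steady", "transient"),
                                  include_velocities = FALSE) {
  mode <- match.arg(mode)
  reg <- feature_registry()
  .with_seed(cfg$seed, {
    blocks <- list()
    for (g in names(cfg$counts)) {
      n <- cfg$counts[[g]]
      cols <- list(animal = sprintf("%s_%02d", g, seq_len(n)),
                   group = rep(g, n))
      for (r in seq_len(nrow(reg))) {
        f <- reg$feature[r]
        pr <- .param_row(params, f, g, mode)
        cols[[f]] <- if (reg$kind[r] == "angle")
          .rnorm_trunc(n, pr$mean, pr$sd, lower = 0, upper = 180)
        else .rpos_norm(n, pr$mean, pr$sd)
      }
      if (include_velocities) {
        vel <- .draw_velocity_block(params, g, mode, n, cfg$asymmetry)
        for (f in names(.VEL_NODE)) cols[[f]] <- vel[, f]
      }
      blocks[[g]] <- as.data.frame(cols, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    attr(out, "mode") <- mode
    out
  })
}

#' @export
print.virtual_animal <- function(x, ...) {
  cat("<virtual_animal> id=", x$id %||% "?", " group=", x$group,
      "; inlet velocities [cm/s]: ",
      paste(sprintf("%s=%.2f", names(x$inlet_velocities),
                    x$inlet_velocities), collapse = ", "), "\n", sep = "")
  invisible(x)
}
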