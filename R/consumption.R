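# Sample-consumption bookkeeping for pulsed liquid-jet delivery.

#' Sample consumption per diffraction image
#'
#' Exact arithmetic: volumes are converted to integer femtoliters
#' internally, so decimal picoliter inputs multiply without floating-point
#' dust (27 pl/shot x 2750 shots = 74.25 nl exactly).
#'
#' @param per_shot_pl Ejected sample volume per shot in picoliters (> 0).
#' @param shots Number of shots averaged per diffraction image (> 0).
#' @return Object of class \code{consumption_estimate} with fields
#'   \code{per_shot_volume} (pl), \code{shots_per_image},
#'   \code{per_image_volume} (nl).
#' @examples
#' consumption(27, 2750)$per_image_volume  # 74.25 nl
#' @export
consumption <- function(per_shot_pl, shots) {
  if (!is.numeric(per_shot_pl) || per_shot_pl <= 0)
    stop("per_shot_pl must be positive")
  if (!is.numeric(shots) || shots <= 0 || shots != round(shots))
    stop("shots must be a positive whole number")
  fl <- per_shot_pl * 1000                     # femtoliters per shot
  if (abs(fl - round(fl)) > 1e-6)
    stop("per_shot_pl must be representable in whole femtoliters")
  total_fl <- round(fl) * shots
  structure(list(per_shot_volume = per_shot_pl,
                 shots_per_image = as.integer(shots),
                 per_image_volume = total_fl / 1e6),
            class = "consumption_estimate")
}

#' @export
print.consumption_estimate <- function(x, ...) {
  cat(sprintf("%g pl/shot x %d shots = %g nl per diffraction image\n",
              x$per_shot_volume, x$shots_per_image, x$per_image_volume))
  invisible(x)
}
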