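Package: srusct
Title: Super-Resolution Ultrasound Track Maps Validated Against Micro-CT Vascular Volumes
Version: 0.1.0
Authors@R: person("srusct", "maintainers", email = "srusct@example.org", role = c("aut", "cre"))
Description: A tested pipeline for forming 2D super-resolution ultrasound
    (ultrasound localization microscopy) microbubble track maps and comparing
    them quantitatively with a 3D micro-CT vascular volume. Provides a
    kidney-like synthetic vascular phantom with simulated microbubble flow,
    tissue motion and a contrast-cast CT volume; microbubble localization,
    speckle-tracking motion compensation and Kalman-gated track linking;
    landmark-based 3D similarity co-registration with slab maximum intensity
    projections and centerline projection; and overlap metrics including ROI
    dilation, mirrored-ROI null controls, 4-s.d. diameter estimation, skeleton
    centerlines, -3 dB line-profile widths and superposed-bundle counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
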