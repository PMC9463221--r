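Package: vclocate
Title: 3D Vena Contracta Localization from Tracked Color-Doppler Intracardiac Echo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated localization of the vena contracta (the narrowest
    neck of a regurgitant jet) from tracked color-Doppler intracardiac
    echocardiography (ICE) frame sequences. Peak-regurgitation frames are
    gated by cardiac cycle, reduced to the Doppler jet by color filtering and
    maximum-intensity-projection compounding, segmented by intensity
    thresholding and largest-island selection, and analyzed by principal
    component analysis to find the minimum jet width (the vena contracta
    width) and its location. The 2D display point is lifted onto the conical
    imaging surface of a forward-looking ICE probe and pushed through the
    probe calibration and electromagnetic-tracking pose transforms into 3D
    tracker space. Includes validation against ground-truth vena contracta
    and annulus point models via closest-distance error with annulus-proximity
    outlier flagging, and a seeded synthetic pulsatile Doppler-sequence
    generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    png,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
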