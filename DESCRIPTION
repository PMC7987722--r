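Package: tmctorque
Title: Thumb Opposition Efficiency from 3D Bone Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based biomechanical modelling of thumb opposition
    efficiency at the trapezio-metacarpal (TMC) joint. Poses a first
    metacarpal against a trapezium, predicts the force of m. opponens
    pollicis with a static four-element Hill-type muscle model under
    several physiological cross-sectional area paradigms, and computes
    joint torques and moment arms for all admissible origin-insertion
    landmark pairs. Quantifies entheseal bone projection with sliding
    semilandmarks, generalized Procrustes superimposition and shape
    principal component analysis, and combines torques and shape in a
    correlation-matrix PCA with out-of-sample projection and a
    torque-on-shape multivariate regression. A seeded synthetic-specimen
    generator provides two species archetypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    vegan,
    jsonlite
Config/testthat/edition: 3
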