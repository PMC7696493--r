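Package: bikephase
Title: Bicycling Phase Recognition for Lower-Limb Prosthesis Sensor Signals
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Recognizes the four phases of a bicycle-crank revolution
    (pedaling, lower buffer, relaxation, upper buffer) from wearable
    kinematic sensors worn on a lower-limb prosthesis. Provides a seeded
    simulator of crank-driven knee/ankle accelerations and knee angle,
    combined soft-hard threshold wavelet-packet denoising, per-sample
    5-D feature extraction, a binary-tree multiclass classifier built
    from three kernel support vector machines with penalty and kernel
    bandwidth tuned by particle swarm optimization under a
    cross-validation fitness, backpropagation and PSO-BP neural-network
    baselines, and the evaluation harness (recognition rate, precision,
    recall, F1, G index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
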