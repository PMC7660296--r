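# Default sensor models. Transfer behaviours are qualitative emulations of
# the tested hardware: the acoustic sensor responds proportionally to surface
# displacement over its 1-100 Hz passband; the piezoelectric diaphragm
# responds to the surface displacement rate low-passed at 10 Hz; the MEMS
# accelerometer reports three axis channels (signal projected on z plus the
# 1 g static offset) band-limited at 50 Hz (first-order, matching the output
# RC caps). Noise floors (Gaussian RMS, volts) are calibration parameters
# tuned once so the detection-threshold study reproduces the observed
# 0.5 / 0.5 / 1.5 mm input thresholds; calibrated, not measured.
sensors:
  - kind: acoustic
    response_mode: displacement
    passband_hz: [1, 100]
    sensitivity: 100.0        # V per m of surface displacement
    noise_floor_rms: 2.0e-3   # V
  - kind: piezoelectric
    response_mode: displacement_rate
    passband_hz: [0.1, 10]
    lowpass_hz: 10
    lowpass_order: 4
    sensitivity: 50.0         # V per m/s of surface displacement rate
    noise_floor_rms: 5.0e-3   # V
  - kind: accelerometer
    response_mode: acceleration
    passband_hz: [0.1, 50]
    bandwidth_hz: 50          # first-order RC limit
    sensitivity: 0.0306       # V per m/s^2 (300 mV/g)
    noise_floor_rms: 1.55e-3  # V per axis
    gravity_offset: true
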