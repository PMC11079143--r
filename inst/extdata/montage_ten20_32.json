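{
  "name": "ten20_32",
  "description": "Idealized unit-sphere 10-20 coordinates for the 32-channel layout (x: right ear, y: nose, z: vertex). Synthetic geometric construction, not digitized electrode positions.",
  "positions": {
    "Fp1": [-0.293892626146237, 0.904508497187474, 0.309016994374947],
    "Fp2": [0.293892626146237, 0.904508497187474, 0.309016994374947],
    "F7": [-0.769420884293813, 0.559016994374947, 0.309016994374947],
    "F3": [-0.492403876506104, 0.586824088833465, 0.642787609686539],
    "Fz": [0, 0.587785252292473, 0.809016994374947],
    "F4": [0.492403876506104, 0.586824088833465, 0.642787609686539],
    "F8": [0.769420884293813, 0.559016994374947, 0.309016994374947],
    "FT9": [-0.951056516295154, 0.309016994374947, 6.12323399573677e-17],
    "FC5": [-0.77685739941951, 0.362254554643694, 0.515038074910054],
    "FC1": [-0.321019760960103, 0.321019760960103, 0.891006524188368],
    "FCz": [0, 0.309016994374947, 0.951056516295154],
    "FC2": [0.321019760960103, 0.321019760960103, 0.891006524188368],
    "FC6": [0.77685739941951, 0.362254554643694, 0.515038074910054],
    "FT10": [0.951056516295154, 0.309016994374947, 6.12323399573677e-17],
    "T7": [-0.951056516295154, 5.82354159244546e-17, 0.309016994374947],
    "C3": [-0.707106781186547, 4.32978028117747e-17, 0.707106781186548],
    "C4": [0.707106781186547, 4.32978028117747e-17, 0.707106781186548],
    "T8": [0.951056516295154, 5.82354159244546e-17, 0.309016994374947],
    "TP9": [-0.951056516295154, -0.309016994374947, 6.12323399573677e-17],
    "CP5": [-0.77685739941951, -0.362254554643694, 0.515038074910054],
    "CP1": [-0.321019760960103, -0.321019760960103, 0.891006524188368],
    "CP2": [0.321019760960103, -0.321019760960103, 0.891006524188368],
    "CP6": [0.77685739941951, -0.362254554643694, 0.515038074910054],
    "TP10": [0.951056516295154, -0.309016994374947, 6.12323399573677e-17],
    "P7": [-0.769420884293813, -0.559016994374947, 0.309016994374947],
    "P3": [-0.492403876506104, -0.586824088833465, 0.642787609686539],
    "Pz": [7.19829327805997e-17, -0.587785252292473, 0.809016994374947],
    "P4": [0.492403876506104, -0.586824088833465, 0.642787609686539],
    "P8": [0.769420884293813, -0.559016994374947, 0.309016994374947],
    "O1": [-0.293892626146237, -0.904508497187474, 0.309016994374947],
    "Oz": [1.16470831848909e-16, -0.951056516295154, 0.309016994374947],
    "O2": [0.293892626146237, -0.904508497187474, 0.309016994374947]
  }
}
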