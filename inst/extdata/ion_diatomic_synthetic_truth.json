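{
  "format": "longrangefit-coefficients-1",
  "units": {
    "energy": "hartree",
    "distance": "bohr",
    "angle": "rad"
  },
  "system": {
    "molA": {
      "name": "ionA",
      "point_group": "Cinfv",
      "charge": 1
    },
    "molB": {
      "name": "diatomB",
      "point_group": "Dinfh",
      "charge": 0
    },
    "relation": "distinct"
  },
  "caps": {
    "elec": 5,
    "ind": 5,
    "disp": 6
  },
  "terms": [
    {
      "interaction": "electrostatic",
      "order": 3,
      "labels": "Q0(A).Q2(B)"
    },
    {
      "interaction": "electrostatic",
      "order": 4,
      "labels": "Q1(A).Q2(B)"
    },
    {
      "interaction": "electrostatic",
      "order": 5,
      "labels": "Q0(A).Q4(B)"
    },
    {
      "interaction": "electrostatic",
      "order": 5,
      "labels": "Q2(A).Q2(B)"
    },
    {
      "interaction": "induction_B",
      "order": 4,
      "labels": "alpha1,1(B).Q0(A).Q0(A)"
    },
    {
      "interaction": "induction_B",
      "order": 5,
      "labels": "alpha1,1(B).Q0(A).Q1(A)"
    },
    {
      "interaction": "dispersion",
      "order": 6,
      "labels": "D[1,1(A);1,1(B)]"
    }
  ],
  "coefficients": {
    "E_asym": 5.2058907291852313e-05,
    "QA.1.1": 0.53984538117614,
    "QA.2.1": -0.034809528754818353,
    "QB.2.1": 0.021187196237144133,
    "QB.4.1": 0.041664975955287259,
    "aB.1_1.1": -0.37902225800236411,
    "aB.1_1.2": -0.18378669936416925,
    "D.1_1|1_1.1.1": -0.063757641445943314,
    "D.1_1|1_1.2.1": 0.0070971525810816808,
    "D.1_1|1_1.1.2": -0.02961193636500593,
    "D.1_1|1_1.2.2": -0.025513419021120514
  }
}
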