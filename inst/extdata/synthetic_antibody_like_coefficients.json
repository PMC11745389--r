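{
  "L": 10,
  "site_labels": ["26", "27", "28", "31", "35", "50", "53", "56", "57", "58"],
  "h": {
    "26": -0.0264818198370754,
    "27": 0.338108229545529,
    "28": 0.292502424949716,
    "31": 0.194765113482845,
    "35": 0.265771353163809,
    "50": -1.11738925399259,
    "53": 1.38291678247042,
    "56": 0.12782398100771,
    "57": -0.176181819490647,
    "58": 0.0787634270575937
  },
  "J": {
    "26,27": -0.158446068829981,
    "26,28": -0.367116604553048,
    "27,28": -0.0256208354834764,
    "26,31": 0.093218150751439,
    "27,31": 0.335711687794103,
    "28,31": 0.124030587169522,
    "26,35": -0.143641923391594,
    "27,35": -0.249304151457177,
    "28,35": 0.320757281591357,
    "31,35": -0.253970871910643,
    "26,50": -1.21062957859745,
    "27,50": -0.0978657056646321,
    "28,50": -0.885048978956237,
    "31,50": -0.683524552323302,
    "35,50": -2.42869380417928,
    "26,53": -0.314502279216838,
    "27,53": 0.0853848399681146,
    "28,53": -0.0742776650014677,
    "31,53": -0.267448628804015,
    "35,53": 0.0108860929909641,
    "50,53": -0.0635083255551492,
    "26,56": -0.147036038598926,
    "27,56": -0.0531257848925754,
    "28,56": 0.209674168707428,
    "31,56": -0.40860598239414,
    "35,56": 0.366718932250625,
    "50,56": -0.0100090767056182,
    "53,56": -0.108612259542055,
    "26,57": -0.196208082480475,
    "27,57": -1.6347052762995,
    "28,57": -0.854253006777022,
    "31,57": -0.725533670885401,
    "35,57": -1.13763023944306,
    "50,57": 0.134302342341383,
    "53,57": -0.196898620306063,
    "56,57": -0.805930047553205,
    "26,58": -0.135415659992246,
    "27,58": 0.322769929176308,
    "28,58": -0.0752779244496808,
    "31,58": 0.000591861569221269,
    "35,58": -0.0907964468259203,
    "50,58": -0.438811578343321,
    "53,58": -0.196708269427397,
    "56,58": 0.0498025500498525,
    "57,58": -0.437364558338601
  },
  "K": {
    "26,27,28": 0.00994426004837516,
    "26,27,31": 0.0116254578891867,
    "26,28,31": -0.109363786674479,
    "27,28,31": -0.111257779293348,
    "26,27,35": 8.25810569707028e-06,
    "26,28,35": -0.0503847479579933,
    "27,28,35": -0.0470707940972965,
    "26,31,35": 0.0351718220702262,
    "27,31,35": -0.0307996139177707,
    "28,31,35": -0.0569144071041811,
    "26,27,50": 0.0625833906744716,
    "26,28,50": 0.563560463175207,
    "27,28,50": 0.245885475860739,
    "26,31,50": 0.106112012660121,
    "27,31,50": -0.141705214736619,
    "28,31,50": -0.788908881540762,
    "26,35,50": -0.130481275538933,
    "27,35,50": 0.401706297068591,
    "28,35,50": -0.64683773121529,
    "31,35,50": -0.106593749287132,
    "26,27,53": -0.671803449138645,
    "26,28,53": 0.824839389965348,
    "27,28,53": 0.323140752191606,
    "26,31,53": 1.22025382020532,
    "27,31,53": 0.731306985804952,
    "28,31,53": 0.11728532145361,
    "26,35,53": 0.458634798550191,
    "27,35,53": -0.126698174602445,
    "28,35,53": 0.000380941776462113,
    "31,35,53": -0.467114071964507,
    "26,50,53": 1.30341813497527,
    "27,50,53": -1.54906375642439,
    "28,50,53": -2.91103824546007,
    "31,50,53": 4.83724776466739,
    "35,50,53": 4.05816879677457,
    "26,27,56": 0.00313312253064645,
    "26,28,56": -0.107571538001393,
    "27,28,56": -0.0762004354217732,
    "26,31,56": 0.00291728938048566,
    "27,31,56": 0.0241204354255308,
    "28,31,56": 0.147915043095985,
    "26,35,56": -0.107173453358749,
    "27,35,56": 0.00899786403980132,
    "28,35,56": -0.0733737698665452,
    "31,35,56": -0.0158092811081057,
    "26,50,56": 0.233358789529957,
    "27,50,56": 0.101093154401007,
    "28,50,56": -0.203712890397526,
    "31,50,56": 0.013752900461241,
    "35,50,56": 1.09115894338279,
    "26,53,56": 0.961314977258376,
    "27,53,56": 1.05191952023273,
    "28,53,56": -0.0113214155600046,
    "31,53,56": 0.654284347494036,
    "35,53,56": 0.0438081153452885,
    "50,53,56": -2.51724631721492,
    "26,27,57": -0.714037608535536,
    "26,28,57": 0.38064709128301,
    "27,28,57": 0.00656212987841613,
    "26,31,57": -0.386725818953641,
    "27,31,57": 0.0791829062374553,
    "28,31,57": -0.355088001800918,
    "26,35,57": -0.284418597051491,
    "27,35,57": -0.0434044634879602,
    "28,35,57": -0.118944212658662,
    "31,35,57": 0.105933801646261,
    "26,50,57": -0.330509906357222,
    "27,50,57": -0.285483835098472,
    "28,50,57": -0.380269366121898,
    "31,50,57": 0.171544080825986,
    "35,50,57": -0.33683814962314,
    "26,53,57": -1.03662391736113,
    "27,53,57": -0.291302807994644,
    "28,53,57": 0.986031069252875,
    "31,53,57": -0.598318498104128,
    "35,53,57": -1.69161800604945,
    "50,53,57": 2.44494246056026,
    "26,56,57": 0.370849432992168,
    "27,56,57": -0.00803127763813974,
    "28,56,57": -0.779766036402347,
    "31,56,57": -0.583670248829647,
    "35,56,57": -0.0205538963046404,
    "50,56,57": 0.216871854137194,
    "53,56,57": 1.05501251886909,
    "26,27,58": -0.0594934766326221,
    "26,28,58": -0.00878131095195611,
    "27,28,58": -0.0383923797505902,
    "26,31,58": -0.0132550845229388,
    "27,31,58": -0.0283301661259548,
    "28,31,58": 0.180012581356037,
    "26,35,58": 0.0013458115424353,
    "27,35,58": -0.0570265537412871,
    "28,35,58": -0.0284967622843828,
    "31,35,58": 0.14319877782736,
    "26,50,58": -0.153333856242013,
    "27,50,58": 1.419248207207,
    "28,50,58": 0.360061814427154,
    "31,50,58": 0.228263917625161,
    "35,50,58": -0.13676663465142,
    "26,53,58": -0.119076819444148,
    "27,53,58": 0.116095894262608,
    "28,53,58": 0.0517277690756355,
    "31,53,58": -0.194454496148659,
    "35,53,58": 0.491655821470423,
    "50,53,58": -3.20384290144862,
    "26,56,58": 0.164724437002211,
    "27,56,58": -0.0250507748222884,
    "28,56,58": 0.00579214209096686,
    "31,56,58": 0.116197480797306,
    "35,56,58": -0.0266483367770985,
    "50,56,58": -0.328199242506189,
    "53,56,58": 0.568962169643469,
    "26,57,58": 0.0972422423356114,
    "27,57,58": -0.0937007350921504,
    "28,57,58": -0.291017558284435,
    "31,57,58": 1.35783821147609,
    "35,57,58": 0.445859602968552,
    "50,57,58": 0.72369892374396,
    "53,57,58": 2.87728907891557,
    "56,57,58": -0.427039348253497
  }
}
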