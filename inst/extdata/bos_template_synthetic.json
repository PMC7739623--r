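{"vertices":[[0.448209,0.3],[0.448119,0.31044],[0.447757,0.352297],[0.447652,0.362816],[0.446502,0.471044],[0.446377,0.482331],[0.445128,0.590263],[0.444767,0.603049],[0.442825,0.642268],[0.441756,0.655563],[0.439345,0.668263],[0.433838,0.693804],[0.428162,0.704833],[0.419387,0.713684],[0.401736,0.715763],[0.365718,0.71762],[0.348444,0.718244],[0.331203,0.718304],[0.254126,0.718485],[0.24027,0.718513],[-0.098581,0.718778],[-0.105985,0.718778],[-0.113363,0.718759],[-0.327512,0.718193],[-0.336179,0.718165],[-0.372189,0.717877],[-0.381419,0.717491],[-0.418731,0.713809],[-0.428402,0.712748],[-0.43612,0.708621],[-0.441116,0.700687],[-0.444482,0.690791],[-0.447201,0.667013],[-0.448135,0.655304],[-0.44887,0.588616],[-0.448955,0.57878],[-0.449642,0.415022],[-0.449658,0.409067],[-0.449508,0.33148],[-0.449497,0.326203],[-0.448643,0.011604],[-0.448387,0.001613],[-0.444252,-0.153109],[-0.440905,-0.165545],[-0.436084,-0.176124],[-0.333646,-0.178414],[-0.324184,-0.178566],[-0.296436,-0.178971],[-0.287377,-0.179091],[-0.208869,-0.179449],[-0.200394,-0.179471],[-0.11646,-0.179643],[-0.108035,-0.179658],[-0.056748,-0.179742],[-0.048027,-0.179743],[0.173462,-0.179552],[0.185722,-0.179461],[0.28091,-0.178575],[0.29606,-0.178341],[0.327748,-0.177748],[0.344245,-0.177287],[0.378172,-0.175568],[0.396003,-0.174633],[0.414165,-0.173391],[0.432006,-0.171299],[0.44202,-0.162537],[0.449052,-0.151418],[0.449241,0.172627],[0.44916,0.183535]],"center":[-0.15,0.3]}
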