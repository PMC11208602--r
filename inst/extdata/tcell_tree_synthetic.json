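{"channels":["CD4","CCR7","CD45RA"],"nodes":[{"name":"Tcells","parent":null},{"name":"CD4","parent":"Tcells","gate":{"CD4":[0.5,null]}},{"name":"CD8","parent":"Tcells","gate":{"CD4":[null,0.5]}},{"name":"CD4_naive","parent":"CD4","gate":{"CCR7":[0.5,null],"CD45RA":[0.5,null]}},{"name":"CD4_TCM","parent":"CD4","gate":{"CCR7":[0.5,null],"CD45RA":[null,0.5]}},{"name":"CD4_TEM","parent":"CD4","gate":{"CCR7":[null,0.5],"CD45RA":[null,0.5]}},{"name":"CD4_TEMRA","parent":"CD4","gate":{"CCR7":[null,0.5],"CD45RA":[0.5,null]}},{"name":"CD8_naive","parent":"CD8","gate":{"CCR7":[0.5,null],"CD45RA":[0.5,null]}},{"name":"CD8_TCM","parent":"CD8","gate":{"CCR7":[0.5,null],"CD45RA":[null,0.5]}},{"name":"CD8_TEM","parent":"CD8","gate":{"CCR7":[null,0.5],"CD45RA":[null,0.5]}},{"name":"CD8_TEMRA","parent":"CD8","gate":{"CCR7":[null,0.5],"CD45RA":[0.5,null]}}],"leaves":[{"name":"CD4_naive","alpha":24.5,"mu":[1,1,1],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD4_TCM","alpha":15,"mu":[1,1,0],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD4_TEM","alpha":7.7,"mu":[1,0,0],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD4_TEMRA","alpha":4.63,"mu":[1,0,1],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD8_naive","alpha":16,"mu":[0,1,1],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD8_TCM","alpha":9,"mu":[0,1,0],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD8_TEM","alpha":16,"mu":[0,0,0],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}},{"name":"CD8_TEMRA","alpha":7.17,"mu":[0,0,1],"sigma":{"CD4":[0.0064,0,0],"CCR7":[0,0.0064,0.002],"CD45RA":[0,0.002,0.0064]}}]}
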