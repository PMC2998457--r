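"consolidated_id","death_confirmed","true_eligible_prd","visit_date"
"C0001",1,1,"2006-04-15"
"C0002",1,1,"2006-04-15"
"C0003",1,1,"2006-04-15"
"C0004",1,1,"2006-04-15"
"C0005",1,1,"2006-04-15"
"C0006",1,1,"2006-04-15"
"C0007",1,1,"2006-04-15"
"C0008",1,1,"2006-04-15"
"C0009",1,1,"2006-04-15"
"C0010",1,1,"2006-04-15"
"C0011",1,1,"2006-04-15"
"C0012",1,1,"2006-04-15"
"C0013",1,1,"2006-04-15"
"C0014",1,1,"2006-04-15"
"C0015",1,1,"2006-04-15"
"C0016",1,1,"2006-04-15"
"C0017",1,1,"2006-04-15"
"C0018",1,1,"2006-04-15"
"C0019",1,1,"2006-04-15"
"C0020",1,1,"2006-04-15"
"C0021",1,1,"2006-04-15"
"C0022",1,1,"2006-04-15"
"C0023",1,1,"2006-04-15"
"C0024",1,1,"2006-04-15"
"C0025",1,1,"2006-04-15"
"C0026",1,0,"2006-04-15"
"C0027",1,0,"2006-04-15"
"C0028",1,0,"2006-04-15"
"C0029",1,0,"2006-04-15"
"C0030",1,0,"2006-04-15"
"C0031",1,0,"2006-04-15"
"C0032",1,0,"2006-04-15"
"C0033",1,0,"2006-04-15"
"C0034",1,0,"2006-04-15"
"C0035",1,0,"2006-04-15"
"C0036",1,0,"2006-04-15"
"C0037",1,0,"2006-04-15"
"C0038",1,0,"2006-04-15"
"C0039",1,0,"2006-04-15"
"C0040",1,0,"2006-04-15"
"C0041",1,0,"2006-04-15"
"C0042",1,0,"2006-04-15"
"C0043",1,0,"2006-04-15"
"C0044",1,0,"2006-04-15"
"C0045",1,0,"2006-04-15"
"C0046",1,0,"2006-04-15"
"C0047",1,0,"2006-04-15"
"C0048",1,0,"2006-04-15"
"C0049",1,0,"2006-04-15"
"C0050",1,0,"2006-04-15"
"C0051",1,0,"2006-04-15"
"C0052",1,0,"2006-04-15"
"C0053",1,0,"2006-04-15"
"C0054",1,0,"2006-04-15"
"C0055",1,0,"2006-04-15"
"C0056",1,0,"2006-04-15"
"C0057",1,0,"2006-04-15"
"C0058",1,0,"2006-04-15"
"C0059",1,0,"2006-04-15"
"C0060",1,0,"2006-04-15"
"C0061",1,0,"2006-04-15"
"C0062",1,0,"2006-04-15"
"C0063",1,0,"2006-04-15"
"C0064",1,0,"2006-04-15"
"C0065",1,0,"2006-04-15"
"C0066",1,0,"2006-04-15"
"C0067",1,0,"2006-04-15"
"C0068",1,0,"2006-04-15"
"C0069",1,0,"2006-04-15"
"C0070",1,0,"2006-04-15"
"C0071",1,0,"2006-04-15"
"C0072",1,0,"2006-04-15"
"C0073",1,0,"2006-04-15"
"C0074",1,0,"2006-04-15"
"C0075",1,0,"2006-04-15"
"C0076",1,0,"2006-04-15"
"C0077",1,0,"2006-04-15"
"C0078",1,0,"2006-04-15"
"C0079",1,0,"2006-04-15"
"C0080",1,0,"2006-04-15"
"C0081",1,0,"2006-04-15"
"C0082",1,0,"2006-04-15"
"C0083",1,0,"2006-04-15"
"C0084",1,0,"2006-04-15"
"C0085",1,0,"2006-04-15"
"C0086",1,0,"2006-04-15"
"C0087",1,0,"2006-04-15"
"C0088",1,0,"2006-04-15"
"C0089",1,0,"2006-04-15"
"C0090",1,0,"2006-04-15"
"C0091",1,0,"2006-04-15"
"C0092",1,0,"2006-04-15"
"C0093",1,0,"2006-04-15"
"C0094",1,0,"2006-04-15"
"C0095",1,0,"2006-04-15"
"C0096",1,0,"2006-04-15"
"C0097",1,0,"2006-04-15"
"C0098",1,0,"2006-04-15"
"C0099",1,0,"2006-04-15"
"C0100",1,0,"2006-04-15"
"C0101",1,0,"2006-04-15"
"C0102",1,0,"2006-04-15"
"C0103",1,0,"2006-04-15"
"C0104",1,0,"2006-04-15"
"C0105",1,0,"2006-04-15"
"C0106",1,0,"2006-04-15"
"C0107",1,0,"2006-04-15"
"C0108",1,0,"2006-04-15"
"C0109",1,0,"2006-04-15"
"C0110",1,0,"2006-04-15"
"C0111",1,0,"2006-04-15"
"C0112",1,0,"2006-04-15"
"C0113",1,0,"2006-04-15"
"C0114",1,0,"2006-04-15"
"C0115",1,0,"2006-04-15"
"C0116",1,0,"2006-04-15"
"C0117",1,0,"2006-04-15"
"C0118",1,0,"2006-04-15"
"C0119",1,0,"2006-04-15"
"C0120",1,0,"2006-04-15"
"C0121",1,0,"2006-04-15"
"C0122",1,0,"2006-04-15"
"C0123",1,0,"2006-04-15"
"C0124",1,0,"2006-04-15"
"C0125",1,0,"2006-04-15"
"C0126",1,0,"2006-04-15"
"C0127",1,0,"2006-04-15"
"C0128",1,0,"2006-04-15"
"C0129",1,0,"2006-04-15"
"C0130",1,0,"2006-04-15"
"C0131",1,0,"2006-04-15"
"C0132",1,0,"2006-04-15"
"C0133",1,0,"2006-04-15"
"C0134",1,0,"2006-04-15"
"C0135",1,0,"2006-04-15"
"C0136",1,0,"2006-04-15"
"C0137",1,0,"2006-04-15"
"C0138",1,0,"2006-04-15"
"C0139",1,0,"2006-04-15"
"C0140",1,0,"2006-04-15"
"C0141",1,0,"2006-04-15"
"C0142",1,0,"2006-04-15"
"C0143",1,0,"2006-04-15"
"C0144",1,0,"2006-04-15"
"C0145",1,0,"2006-04-15"
"C0146",1,0,"2006-04-15"
"C0147",1,0,"2006-04-15"
"C0148",1,0,"2006-04-15"
"C0149",1,0,"2006-04-15"
"C0150",1,0,"2006-04-15"
"C0151",1,0,"2006-04-15"
"C0152",1,0,"2006-04-15"
"C0153",1,0,"2006-04-15"
"C0154",1,0,"2006-04-15"
"C0155",1,0,"2006-04-15"
"C0156",1,0,"2006-04-15"
"C0157",1,0,"2006-04-15"
"C0158",1,0,"2006-04-15"
"C0159",1,0,"2006-04-15"
"C0160",1,0,"2006-04-15"
"C0161",1,0,"2006-04-15"
"C0162",1,0,"2006-04-15"
"C0163",1,0,"2006-04-15"
"C0164",1,0,"2006-04-15"
"C0165",1,0,"2006-04-15"
"C0166",1,0,"2006-04-15"
"C0167",1,0,"2006-04-15"
"C0168",1,0,"2006-04-15"
"C0169",1,0,"2006-04-15"
"C0170",1,0,"2006-04-15"
"C0171",1,0,"2006-04-15"
"C0172",1,0,"2006-04-15"
"C0173",1,0,"2006-04-15"
"C0174",1,0,"2006-04-15"
"C0175",1,0,"2006-04-15"
"C0176",1,0,"2006-04-15"
"C0177",1,0,"2006-04-15"
"C0178",1,0,"2006-04-15"
"C0179",1,0,"2006-04-15"
"C0180",1,0,"2006-04-15"
"C0181",1,0,"2006-04-15"
"C0182",1,0,"2006-04-15"
"C0183",1,0,"2006-04-15"
"C0184",1,0,"2006-04-15"
"C0185",1,0,"2006-04-15"
"C0186",1,0,"2006-04-15"
"C0187",1,0,"2006-04-15"
"C0188",1,0,"2006-04-15"
"C0189",1,0,"2006-04-15"
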