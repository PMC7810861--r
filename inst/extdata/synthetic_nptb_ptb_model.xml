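<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
<model id="grn_model" name="Shea-Ackers neural conversion GRN">
<annotation>
<grn:network xmlns:grn="https://grnconv.r-pkg/annotation">
<grn:node id="PTB" beta="true"/>
<grn:node id="nPTB" beta="false"/>
<grn:node id="miRs" beta="true"/>
<grn:node id="RESTc" beta="true"/>
<grn:node id="Ascl1" beta="false"/>
<grn:edge source="miRs" target="PTB" sign="inhibition"/>
<grn:edge source="miRs" target="nPTB" sign="inhibition"/>
<grn:edge source="PTB" target="nPTB" sign="inhibition"/>
<grn:edge source="miRs" target="RESTc" sign="inhibition"/>
<grn:edge source="PTB" target="RESTc" sign="activation"/>
<grn:edge source="RESTc" target="miRs" sign="inhibition"/>
<grn:edge source="RESTc" target="Ascl1" sign="inhibition"/>
<grn:edge source="nPTB" target="PTB" sign="activation"/>
<grn:input id="RESTi" target="RESTc" sign="inhibition" active="true"/>
<grn:input id="vAscl1" target="miRs" sign="activation" active="true"/>
</grn:network>
</annotation>
<listOfCompartments><compartment id="cell" constant="true" size="1"/></listOfCompartments>
<listOfSpecies>
<species id="PTB" compartment="cell" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="nPTB" compartment="cell" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="miRs" compartment="cell" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="RESTc" compartment="cell" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="Ascl1" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
</listOfSpecies>
<listOfParameters>
<parameter id="alpha_PTB" value="0.114259986396161098" constant="true"/>
<parameter id="alpha_nPTB" value="0.797635614102111146" constant="true"/>
<parameter id="alpha_miRs" value="2.678278885350605432" constant="true"/>
<parameter id="alpha_RESTc" value="0.362285882816736071" constant="true"/>
<parameter id="alpha_Ascl1" value="0.136524689726845033" constant="true"/>
<parameter id="delta_PTB" value="0.042381958973216657" constant="true"/>
<parameter id="delta_nPTB" value="0.044188525635433504" constant="true"/>
<parameter id="delta_miRs" value="0.419620009409077011" constant="true"/>
<parameter id="delta_RESTc" value="0.281468105790046774" constant="true"/>
<parameter id="delta_Ascl1" value="0.101752593446912176" constant="true"/>
<parameter id="beta_PTB" value="0.046936969234186110" constant="true"/>
<parameter id="beta_miRs" value="0.771299358114983957" constant="true"/>
<parameter id="beta_RESTc" value="0.475323564858811221" constant="true"/>
<parameter id="k_miRs_PTB" value="1.406214906204210413" constant="true"/>
<parameter id="k_miRs_nPTB" value="5.490962586721051863" constant="true"/>
<parameter id="k_PTB_nPTB" value="0.476936332651547001" constant="true"/>
<parameter id="k_miRs_RESTc" value="1.097701232877424715" constant="true"/>
<parameter id="k_PTB_RESTc" value="0.640578538795633201" constant="true"/>
<parameter id="k_RESTc_miRs" value="0.329139054857856161" constant="true"/>
<parameter id="k_RESTc_Ascl1" value="0.191527497722339096" constant="true"/>
<parameter id="k_nPTB_PTB" value="1.062947528537629305" constant="true"/>
<parameter id="h_miRs_PTB" value="2.599831066617486641" constant="true"/>
<parameter id="h_miRs_nPTB" value="1.137363030840816247" constant="true"/>
<parameter id="h_PTB_nPTB" value="3.819301286417994046" constant="true"/>
<parameter id="h_miRs_RESTc" value="2.337937641948954592" constant="true"/>
<parameter id="h_PTB_RESTc" value="3.950000000000000178" constant="true"/>
<parameter id="h_RESTc_miRs" value="1.032972156730438185" constant="true"/>
<parameter id="h_RESTc_Ascl1" value="3.430350152903057115" constant="true"/>
<parameter id="h_nPTB_PTB" value="3.950000000000000178" constant="true"/>
<parameter id="beta_RESTi" value="2.460350496252758923" constant="true"/>
<parameter id="beta_vAscl1" value="3.745450523310778213" constant="true"/>
</listOfParameters>
<listOfRules>
<rateRule variable="PTB">
<math xmlns="http://www.w3.org/1998/Math/MathML">
<apply><minus/><apply><times/><ci> alpha_PTB </ci><apply><divide/><apply><plus/><ci> beta_PTB </ci><apply><power/><apply><divide/><ci> nPTB </ci><ci> k_nPTB_PTB </ci></apply><ci> h_nPTB_PTB </ci></apply></apply><apply><plus/><cn> 1 </cn><ci> beta_PTB </ci><apply><power/><apply><divide/><ci> nPTB </ci><ci> k_nPTB_PTB </ci></apply><ci> h_nPTB_PTB </ci></apply><apply><power/><apply><divide/><ci> miRs </ci><ci> k_miRs_PTB </ci></apply><ci> h_miRs_PTB </ci></apply></apply></apply></apply><apply><times/><ci> delta_PTB </ci><ci> PTB </ci></apply></apply>
</math>
</rateRule>
<rateRule variable="nPTB">
<math xmlns="http://www.w3.org/1998/Math/MathML">
<apply><minus/><apply><times/><ci> alpha_nPTB </ci><apply><divide/><cn> 1 </cn><apply><plus/><cn> 1 </cn><apply><power/><apply><divide/><ci> miRs </ci><ci> k_miRs_nPTB </ci></apply><ci> h_miRs_nPTB </ci></apply><apply><power/><apply><divide/><ci> PTB </ci><ci> k_PTB_nPTB </ci></apply><ci> h_PTB_nPTB </ci></apply></apply></apply></apply><apply><times/><ci> delta_nPTB </ci><ci> nPTB </ci></apply></apply>
</math>
</rateRule>
<rateRule variable="miRs">
<math xmlns="http://www.w3.org/1998/Math/MathML">
<apply><minus/><apply><times/><ci> alpha_miRs </ci><apply><divide/><apply><plus/><ci> beta_miRs </ci><ci> beta_vAscl1 </ci></apply><apply><plus/><cn> 1 </cn><ci> beta_miRs </ci><ci> beta_vAscl1 </ci><apply><power/><apply><divide/><ci> RESTc </ci><ci> k_RESTc_miRs </ci></apply><ci> h_RESTc_miRs </ci></apply></apply></apply></apply><apply><times/><ci> delta_miRs </ci><ci> miRs </ci></apply></apply>
</math>
</rateRule>
<rateRule variable="RESTc">
<math xmlns="http://www.w3.org/1998/Math/MathML">
<apply><minus/><apply><times/><ci> alpha_RESTc </ci><apply><divide/><apply><plus/><ci> beta_RESTc </ci><apply><power/><apply><divide/><ci> PTB </ci><ci> k_PTB_RESTc </ci></apply><ci> h_PTB_RESTc </ci></apply></apply><apply><plus/><cn> 1 </cn><ci> beta_RESTc </ci><apply><power/><apply><divide/><ci> PTB </ci><ci> k_PTB_RESTc </ci></apply><ci> h_PTB_RESTc </ci></apply><apply><power/><apply><divide/><ci> miRs </ci><ci> k_miRs_RESTc </ci></apply><ci> h_miRs_RESTc </ci></apply><ci> beta_RESTi </ci></apply></apply></apply><apply><times/><ci> delta_RESTc </ci><ci> RESTc </ci></apply></apply>
</math>
</rateRule>
<rateRule variable="Ascl1">
<math xmlns="http://www.w3.org/1998/Math/MathML">
<apply><minus/><apply><times/><ci> alpha_Ascl1 </ci><apply><divide/><cn> 1 </cn><apply><plus/><cn> 1 </cn><apply><power/><apply><divide/><ci> RESTc </ci><ci> k_RESTc_Ascl1 </ci></apply><ci> h_RESTc_Ascl1 </ci></apply></apply></apply></apply><apply><times/><ci> delta_Ascl1 </ci><ci> Ascl1 </ci></apply></apply>
</math>
</rateRule>
</listOfRules>
</model>
</sbml>
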